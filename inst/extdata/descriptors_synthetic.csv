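# SYNTHETIC stand-in descriptor table: RBN and B04[N-Si] are computed from the 20-unit oligomer graphs; all other columns are simulated (simulate_descriptor_table(), seed 20260922) and carry no measured structural information.
code,RBN,B04[N-Si],MATS7i,SpMAD_AEA(dm),SpMAD_AEA(bo),SpMax_B(s),H5u,R3u+,Mor02v,Mor10v,Mor10m,Mor12m,Mor04p,BLTF96
OV-1,42,0,-0.008687953408184974,0.22129716289706264,0.0927269790690855,4.606009901542203,1.7513924186226453,0.023016368065157514,-49.86481441280689,-2.636040502131352,-8.853900382040703,-3.588908941175306,-0.7993464389789935,-15.135157816082014
SE-52,43,0,0.0222435958518396,0.1632066416085847,0.07914569553346848,5.00008208799174,1.8091792636723596,0.01898378731105725,-3.8128380995233186,-4.2740599614309005,-5.647243009130191,-1.8243912376170242,13.102435608238522,-11.636697916920996
OV-3,46,0,0.011586256988384126,0.1714659689283153,0.11607706210258771,4.134482055842981,1.5621289900764816,0.021759323581066383,-27.528958997090005,-4.6985673300938355,-10.466750522434781,-9.357272185176758,16.748564364976225,-16.612193409993356
OV-7,50,0,0.03358123821864138,0.11952121897755147,0.10868607233148458,5.145183871466351,1.9976679925210923,0.019681057627788247,-44.05673144923315,-1.3648677732363659,-10.454424114972106,-4.359016946989071,12.694879397526467,-8.636901174375565
DC-550,52,0,-0.024198994447257576,0.10777244737835906,0.08132395543703683,4.222755576281227,1.982233243444531,0.01864119615977476,-35.286024616697084,-5.127149821046902,-4.988260809108323,-5.360202449688238,-1.7847268929051197,-8.014421564457837
OV-11,56,0,0.03558957451058185,0.156600376995255,0.10046296952226763,2.917623143332314,2.364155211876194,0.019827451925898625,-2.2625337326347967,-4.290573672939504,-7.782389603127419,-0.6201161331158955,2.8432662141902316,-14.51892463317305
OV-17,62,0,0.005983615610559571,0.10552479026695114,0.08528039089277889,4.799183027135024,1.9091973686091994,0.019426898266570534,-4.128053527673103,-6.589784965378893,-5.910728904249219,-6.154624651666747,13.597055019274855,-7.65899744790598
SP-392,64,0,0.018466988716606327,0.15929009212125936,0.14631684180405433,2.9736695656526324,1.1477283788919257,0.021956834689977524,-42.14814949495498,-5.056322002361112,-3.8329274961416724,-5.640949989415347,7.974007284647252,-7.748601199063709
OV-22,68,0,0.026274969512944325,0.08021153776515623,0.08690209719394232,3.71843465517206,1.444212063620198,0.01815135998762136,-36.30431728700912,-1.772175688527597,-6.891492731674555,-0.5005798440125995,8.833930969957702,-12.458577466106348
OV-25,72,0,0.015144609427465306,0.2103823613856839,0.031091587372582052,2.1974157124732017,3.265590787599954,0.02007203036639368,-52.76707713718432,-2.551158451530546,-7.895890005857259,-7.650232029387007,5.926450513533072,-16.26830373517909
Rtx-20,50,0,-0.004270039752953127,0.1700062208629351,0.1179631378879539,4.885808417278496,1.8908895633732747,0.016079767415166455,-26.762915515519424,-3.7698754668577044,-12.393909349413597,-3.3804594346804056,8.43502450817317,-12.664869182105651
OV-61,56,0,0.026259787398163734,0.08754435827979987,0.133107462012862,2.604943577488661,1.900116824960469,0.019116620466574977,-9.42353750672632,-5.621510891787547,-10.214439624750643,-10.306152294104699,7.322231319141549,-11.079952902264825
Rtx-35,56,0,0.02435828484265496,0.03392253754427986,0.0907273186671628,4.8457585172356605,2.3956705072987496,0.019800022909563533,-17.733410043946677,-6.732570299235452,-6.457952261087689,-5.852963030088053,15.157612652898681,-1.5784569102106687
Rtx-65,68,0,0.02635869278298346,0.14533535065444178,0.1146222112108771,3.4066857461707274,1.8272803039492151,0.024550849584487583,-34.301942273655335,-5.202719050976223,-9.919727619778634,-3.1759268546971215,14.292626619736238,-11.455825488290278
OV-210,102,0,0.03302405527009408,0.14759212684074993,0.08949793882456915,5.757988429354408,2.081921339354536,0.022977482804668665,-16.977896364684394,-6.41610981010971,-8.339367441882516,-9.849462568255948,7.048471488201125,-14.498958729910104
SKIFT-50X,72,0,0.023296334268423584,0.12327983546022733,0.09643022224469464,6.257089398306221,2.2174248340992135,0.018700869776896358,-17.366925446397772,-7.388422640872382,-10.187382870577121,-8.759363835925546,0.22468192927633623,-13.976893331892548
FS-328,60,0,5.371377237897573e-4,0.22693654851355827,0.15578239841262995,4.2815379386562595,2.5639439594296496,0.019613087656598957,-1.6809395929433606,-7.2242613533929925,-8.858354584835563,-8.040842074789168,4.536240421718609,-7.658949796307961
FS-169,57,0,0.03133847181217343,0.1777129052752584,0.10013017065003868,5.9672176381026425,2.7379464439720933,0.017506708696268962,-6.844283140635245,-3.894908032560729,-8.000229475498479,-12.313261660322931,1.2690382365425528,-9.590847660547071
SILAR 5CP,122,0,0.0245416827796741,0.09930428217635907,0.08890772868048136,3.422381490707146,2.216274555171856,0.019070122644867116,-34.46429288692848,-4.301259067524269,-8.27600060288384,-12.947515754226895,14.263418456428935,-9.241272213807296
SILAR 7CP,142,0,0.033795123901299774,0.09354390057120521,0.06259489190774893,1.6871253564654607,1.7752054583750274,0.020435296453370326,-6.002929203669943,-8.631554429246917,-7.095342191827301,-8.924771990295792,15.776891745408175,-5.269821629761665
SILAR 9CP,154,0,0.03425292756647295,0.12433227598202083,0.10504601094879935,3.988761673644563,1.631647967556002,0.023199862969114502,-29.524320748192064,-4.048512128441886,-9.517237415219684,-7.828761362628685,5.310441112344939,-12.613943873454836
SILAR 10CP,162,0,0.03086047764643209,0.193034353735388,0.0802374384296505,2.7391639095852263,1.1675681994101803,0.020837534125336225,-27.852593308539486,-8.290901063743918,-10.170692735328501,-9.561858210976588,7.864728211199459,-12.79583396460986
OV-105,48,0,0.004827287881854216,0.18833820164800408,0.11680593363761084,4.1850066101376155,2.3076814211687626,0.017597098671356094,-6.8844560337532315,-5.125248686438299,-10.367225909540316,-1.5516351349883717,5.985732952843224,-13.130328224112745
OV-225,82,0,0.007447746309621375,0.1632348986614035,0.06709512229141157,3.4386447196268954,0.6541114033359847,0.020686941189842024,-5.9252327991395575,-7.55933910787318,-8.25227114030437,-5.130199499767583,7.1222934420447075,-5.7441596974640605
p-NSKT-100,102,0,0.017569720386248194,0.0878229054426074,0.1088198840469315,5.513243582243607,1.5978674040369818,0.017259332239199735,-47.68221730742967,-6.854747562645018,-4.457577397928089,-4.154030589845369,5.110723984998202,-8.967438167784763
NPS-100,82,1,0.008519144341984848,0.08171958466471586,0.052248542925647325,3.8706571229073212,1.9754911421003423,0.018108987035456513,-26.695420135701706,-5.718512310855306,-9.528321373961022,-11.261561301473586,15.520165905132469,-9.83201137524489
NSKI-25,52,1,0.011185089174076407,0.2106500113726996,0.10807504367714824,6.1523611454639395,2.474239013751104,0.01842579400412158,-9.543830622057751,-8.062782310491,-6.893300871622601,-9.19094529418851,18.433131264868873,-11.136734304052567
NSKT-33,56,1,0.018268684637510326,0.1638950635282505,0.0906434768907291,3.260641678028524,1.5037850868196294,0.016398392479917315,-14.398152178473502,-3.653061905324833,-13.01330790683702,-5.396079956968502,-1.5331570831680992,-7.741075292553425
XE-60,62,1,0.033901066188928394,0.2527952010686654,0.08924723355560535,2.395122179730685,2.5972192847939324,0.024369657183392877,-18.022013482825656,-10.058890133858267,-6.402879309824538,-5.1169779314133095,15.133245943799588,-6.606926742275984
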