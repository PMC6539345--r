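# Regenerates inst/extdata/descriptors_synthetic.csv, the synthetic stand-in
# descriptor table (RBN and B04[N-Si] computed from the oligomer graphs, the
# twelve geometry/spectrum descriptors simulated at the default seed).
devtools::load_all(".")
tab <- simulate_descriptor_table()
header <- paste(
  "# SYNTHETIC stand-in descriptor table: RBN and B04[N-Si] are computed",
  "from the 20-unit oligomer graphs; all other columns are simulated",
  "(simulate_descriptor_table(), seed 20260922) and carry no measured",
  "structural information.")
body <- readr::format_csv(tab)
cat(header, "\n", body, sep = "",
    file = "inst/extdata/descriptors_synthetic.csv")

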