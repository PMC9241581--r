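# Regenerates the shipped extdata fixtures from the in-code builders.
# Run from the package root: Rscript data-raw/build_fixtures.R

devtools::load_all(".", quiet = TRUE)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

uk <- uk_inputs()
ch <- china_inputs()

write_inputs(uk, "inst/extdata/inputs_uk.json")
write_inputs(ch, "inst/extdata/inputs_china.json")
write_life_table(uk$life_table, "inst/extdata/life_table_uk_synthetic.csv")
write_life_table(ch$life_table, "inst/extdata/life_table_china_synthetic.csv")

cat("wrote", length(uk$arms), "UK arms and", length(ch$arms), "China arms\n")
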