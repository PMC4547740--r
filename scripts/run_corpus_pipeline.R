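#!/usr/bin/env Rscript
# Thin shell entry point over adrcorpus::run_pipeline(): generates a
# synthetic cohort, mines and samples a corpus, simulates the rater panel,
# classifies, and writes corpus.xml + manifest.json to --out-dir.
#
#   Rscript scripts/run_corpus_pipeline.R --seed 1 --out-dir corpus_out \
#       [--n-patients 60] [--span-days 365] [--sample-size 400] \
#       [--p-effect 0.33] [--n-raters 11] [--reliability 0.9] [--verbose]

suppressPackageStartupMessages({
  library(adrcorpus)
  library(optparse)
})

parser <- OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out-dir", dest = "out_dir", type = "character",
              default = "corpus_out"),
  make_option("--n-patients", dest = "n_patients", type = "integer",
              default = 60L),
  make_option("--span-days", dest = "span_days", type = "integer",
              default = 365L),
  make_option("--sample-size", dest = "sample_size", type = "integer",
              default = 400L),
  make_option("--p-effect", dest = "p_effect", type = "double",
              default = 0.33),
  make_option("--n-raters", dest = "n_raters", type = "integer",
              default = 11L),
  make_option("--reliability", type = "double", default = 0.9),
  make_option("--verbose", action = "store_true", default = FALSE)
))
opt <- parse_args(parser)

status <- tryCatch({
  mf <- run_pipeline(
    gen_config = generator_config(n_patients = opt$n_patients,
                                  span_days = opt$span_days,
                                  p_effect = opt$p_effect),
    pipe_config = pipeline_config(sample_size = opt$sample_size),
    profiles = rater_profiles(opt$n_raters, reliability = opt$reliability),
    seed = opt$seed, out_dir = opt$out_dir, verbose = opt$verbose)
  print(mf)
  print(mf$summary)
  0L
}, adrcorpus_validation_error = function(e) {
  message("validation error: ", conditionMessage(e)); 2L
}, adrcorpus_config_error = function(e) {
  message("configuration error: ", conditionMessage(e)); 2L
}, error = function(e) {
  message("error: ", conditionMessage(e)); 1L
})
quit(status = status)
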