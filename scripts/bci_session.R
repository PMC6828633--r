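#!/usr/bin/env Rscript
# Thin command-line front end over the coadaptBCI package.
#
#   Rscript scripts/bci_session.R synth   --out session.rds --seed 1 [--tpc 190] [--erd 0.2]
#   Rscript scripts/bci_session.R replay  --session session.rds --policy supervised --out result.rds
#   Rscript scripts/bci_session.R compare --session session.rds --out compared.rds

suppressMessages({
  library(optparse)
  library(coadaptBCI)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args)) args[1] else ""
rest <- args[-1]

opt_list <- list(
  make_option("--out", type = "character", default = NULL),
  make_option("--session", type = "character", default = NULL),
  make_option("--policy", type = "character", default = "supervised"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--tpc", type = "integer", default = 190L),
  make_option("--erd", type = "double", default = 0.2)
)
opts <- parse_args(OptionParser(option_list = opt_list), args = rest)

load_labelled <- function(path) {
  s <- load_session(path)
  if (is.null(s$labels)) s$labels <- s$rec$events$code
  s
}

if (cmd == "synth") {
  ses <- generate_session(synth_config(seed = opts$seed, n_tpc = opts$tpc,
                                       erd_depth = opts$erd))
  save_session(ses$rec, opts$out, labels = ses$labels)
  cat("wrote", opts$out, ":", length(ses$labels), "trials\n")
} else if (cmd == "replay") {
  s <- load_labelled(opts$session)
  pol <- retrain_policy(opts$policy)
  res <- run_session(s$rec, s$labels, pol, seed = opts$seed)
  saveRDS(res, opts$out)
  print(res)
  print(retrain_log(res))
  print(accuracy_timecourse(res))
} else if (cmd == "compare") {
  s <- load_labelled(opts$session)
  cmp <- run_comparison(s$rec, s$labels, seed = opts$seed)
  saveRDS(cmp, opts$out)
  print(cmp$summary)
} else {
  stop("usage: bci_session.R {synth|replay|compare} [options]")
}
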