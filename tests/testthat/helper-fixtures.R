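# fixtures are generated in code; the uncensored reference cohort is the one
# used by the concordance checks
fixture_uncensored <- function(n = 50, seed = 7) {
  sim_weibull_gamma(n, median1 = 3, ratio_R = 1.3, kappa = 1, theta = 1,
                    seed = seed)
}

tiny_cohort <- function() {
  as_cohort(data.frame(id = c("a", "b", "c", "d"),
                       pfs1 = c(3, 2, 4, 5),
                       pfs2 = c(6, 2, 1, 4),
                       event2 = c(1, 0, 1, 1)))
}

ratio_sample_of <- function(ratio, event, anchor = NULL) {
  if (is.null(anchor)) anchor <- rep(1, length(ratio))
  structure(data.frame(ratio = ratio, event = event, pfs1_anchor = anchor),
            class = c("ratio_sample", "data.frame"))
}

write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
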