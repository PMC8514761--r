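# Shared fixtures built in code at test time.

tiny_table <- function(scale = "raw") {
  ev <- matrix(c(100, 5, 2000,
                 120, 8, 1800,
                 90, 4, 2200),
               nrow = 3, byrow = TRUE,
               dimnames = list(NULL, c("CD45", "EpCAM", "pdpn")))
  tab <- event_table(ev, sample_id = "tiny")
  if (scale == "transformed") tab <- transform_events(tab) else tab
}

write_tiny_csv <- function(path, header = "CD45,EpCAM,pdpn") {
  writeLines(c(header, "100,5,2000", "120,8,1800", "90,4,2200"), path)
  path
}

# full-panel spec for exact-recovery checks: tight log-scale sd plus
# truncation makes every decision boundary's populations strictly disjoint
separated_sample_spec <- function(n = 2000, seed = 42) {
  sample_spec(default_population_models(sigma = 0.15, truncate_sigma = 3),
              n, seed = seed)
}

# small expression spec whose planted/housekeeping totals fit tiny matrices
small_expression_spec <- function(n_genes, seed, ...) {
  expression_spec(n_genes = n_genes, seed = seed,
                  planted_exclusive = c(mTEC = 15L, cTEC = 6L, FB = 5L, EC = 4L),
                  housekeeping_count = 10L, ...)
}

# hand-built 3-reference / 2-sample Ct fixture with known folds
ddct_fixture <- function() {
  data.frame(
    gene = rep(c("AIRE", "GAPDH", "HPRT-1", "RPLP13"), times = 2),
    sample = rep(c("cal", "s2"), each = 4),
    ct = c(30, 20, 22, 24,    # cal: dCt = 30 - 22 = 8
           27, 19.5, 21.5, 23.5))  # s2: dCt = 27 - 21.5 = 5.5; ddCt = -2.5
}
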