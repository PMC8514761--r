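# Synthetic FPKM matrices with planted population-exclusive genes,
# housekeeping genes, shared genes and silent background.

#' Expression matrix specification
#'
#' Emulates the sorted-subset bulk expression data behind the
#' exclusive-transcript analysis. Planted exclusive genes are "on"
#' (log-normal FPKM above threshold, subject to per-sample dropout) only in
#' their population; housekeeping genes are on in every population; a
#' configurable fraction of the remaining genes is shared-on in two or more
#' populations and the rest is silent (uniform on [0, background_max]).
#' Default planted counts scale the published per-population exclusive
#' counts (841 mTEC / 128 cTEC / 227 FB / 104 EC) down by five to fit a
#' 2,000-gene matrix.
#'
#' @param n_genes Number of genes (default 2000).
#' @param samples_per_population Named integer vector (default
#'   cTEC 6, mTEC 6, FB 4, EC 4).
#' @param planted_exclusive Named integer vector population -> number of
#'   planted exclusive genes.
#' @param housekeeping_count Number of planted housekeeping genes.
#' @param shared_prob Probability that a non-planted gene is shared-on
#'   (in >= 2 populations) rather than silent.
#' @param expressed_mu,expressed_sigma Log-normal parameters of "on" FPKM.
#' @param background_max Ceiling of silent/background FPKM; must stay below
#'   the calling threshold in force.
#' @param dropout_prob Probability that an "on" gene falls to background in a
#'   given sample.
#' @param seed RNG seed.
#' @return An `ExpressionSpec`.
#' @export
expression_spec <- function(n_genes = 2000L,
                            samples_per_population = c(cTEC = 6L, mTEC = 6L,
                                                       FB = 4L, EC = 4L),
                            planted_exclusive = c(mTEC = 168L, cTEC = 26L,
                                                  FB = 45L, EC = 21L),
                            housekeeping_count = 100L,
                            shared_prob = 0.3,
                            expressed_mu = log(10), expressed_sigma = 1,
                            background_max = 0.4,
                            dropout_prob = 0, seed = 1L) {
  if (sum(planted_exclusive) + housekeeping_count > n_genes) {
    stop("config error: planted + housekeeping exceeds n_genes", call. = FALSE)
  }
  stopifnot(background_max >= 0, dropout_prob >= 0, dropout_prob < 1,
            all(names(planted_exclusive) %in% names(samples_per_population)))
  structure(list(n_genes = as.integer(n_genes),
                 samples_per_population = samples_per_population,
                 planted_exclusive = planted_exclusive,
                 housekeeping_count = as.integer(housekeeping_count),
                 shared_prob = shared_prob,
                 expressed_mu = expressed_mu, expressed_sigma = expressed_sigma,
                 background_max = background_max,
                 dropout_prob = dropout_prob, seed = seed),
            class = "ExpressionSpec")
}

#' Simulate an FPKM expression matrix with planted truth
#'
#' @param spec An `ExpressionSpec`.
#' @return List with `matrix` (an `ExpressionMatrix`) and `truth` (list:
#'   `exclusive` population -> planted gene ids, `housekeeping`, `shared`).
#' @export
simulate_expression_matrix <- function(spec) {
  stopifnot(inherits(spec, "ExpressionSpec"))
  pops <- names(spec$samples_per_population)
  samples <- unlist(lapply(pops, function(p) {
    sprintf("%s_%d", p, seq_len(spec$samples_per_population[[p]]))
  }))
  sample_pop <- stats::setNames(rep(pops, spec$samples_per_population), samples)
  genes <- sprintf("G%05d", seq_len(spec$n_genes))

  with_seed(spec$seed, {
    # partition genes: planted exclusive blocks, housekeeping, then the rest
    idx <- seq_len(spec$n_genes)
    planted <- list()
    cursor <- 0L
    for (p in names(spec$planted_exclusive)) {
      k <- spec$planted_exclusive[[p]]
      planted[[p]] <- genes[cursor + seq_len(k)]
      cursor <- cursor + k
    }
    hk <- genes[cursor + seq_len(spec$housekeeping_count)]
    cursor <- cursor + spec$housekeeping_count
    rest <- genes[idx > cursor]

    # on/off pattern per gene x population
    on <- matrix(FALSE, spec$n_genes, length(pops),
                 dimnames = list(genes, pops))
    for (p in names(planted)) on[planted[[p]], p] <- TRUE
    on[hk, ] <- TRUE
    shared <- character(0)
    if (length(rest)) {
      is_shared <- stats::runif(length(rest)) < spec$shared_prob
      shared <- rest[is_shared]
      for (g in shared) {
        k <- sample(2:length(pops), 1L)
        on[g, sample(pops, k)] <- TRUE
      }
    }

    vals <- matrix(stats::runif(spec$n_genes * length(samples),
                                0, spec$background_max),
                   nrow = spec$n_genes,
                   dimnames = list(genes, samples))
    for (p in pops) {
      cols <- which(sample_pop == p)
      rows <- which(on[, p])
      if (!length(rows)) next
      k <- length(rows) * length(cols)
      expr <- stats::rlnorm(k, spec$expressed_mu, spec$expressed_sigma)
      if (spec$dropout_prob > 0) {
        drop <- stats::runif(k) < spec$dropout_prob
        expr[drop] <- stats::runif(sum(drop), 0, spec$background_max)
      }
      vals[rows, cols] <- matrix(expr, length(rows), length(cols))
    }
    list(matrix = expression_matrix(vals, sample_pop),
         truth = list(exclusive = planted, housekeeping = hk, shared = shared))
  })
}
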