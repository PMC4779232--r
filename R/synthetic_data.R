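#' Balanced simulation design
#'
#' Convenience builder for a design with the same number of case-control
#' pairs in every stratum x time-period cell.
#'
#' @param strata Character vector of stratum labels.
#' @param n_periods Number of time periods (1 = nearest diagnosis).
#' @param pairs_per_period Pairs per stratum per period.
#' @return Data.frame with columns `stratum`, `time_period`, `n_pairs`.
#' @export
uniform_design <- function(strata = "S1", n_periods = 3L, pairs_per_period = 20L) {
  d <- expand.grid(time_period = seq_len(n_periods), stratum = strata,
                   stringsAsFactors = FALSE)
  data.frame(stratum = d$stratum, time_period = as.integer(d$time_period),
             n_pairs = as.integer(pairs_per_period), stringsAsFactors = FALSE)
}

#' Configuration for the paired-difference generator
#'
#' The generator emulates the statistical structure the curve-group method
#' assumes: per pair p and gene g,
#' `X[g, p] = mu[g, t(p), s(p)] + b_g * f_p + eps[g, p]`, with independent
#' Gaussian noise `eps ~ N(0, noise_sd^2)`, a standard-normal pair-level
#' latent factor `f_p` with gene loadings `b_g ~ N(0, factor_loading_sd^2)`
#' inducing inter-gene correlation within a pair, and planted per-period
#' means for signal genes. A signal gene with curve-group label c has
#' `mu = delta * (rank of the period in c - (T+1)/2)` in its signal strata
#' (centred, so signal genes have zero marginal mean and the time effect is
#' isolated), optionally plus a constant `stratum_shift`. Background genes
#' have mean zero everywhere.
#'
#' @param n_genes Number of genes.
#' @param design Data.frame with columns `stratum`, `time_period`, `n_pairs`
#'   (all counts at least 2); see [uniform_design()].
#' @param n_signal Number of signal genes (the first `n_signal` gene ids).
#' @param signal_labels Curve-group label(s) for the signal genes, recycled.
#' @param delta Spacing (log2 units) between consecutive planted rank levels.
#' @param noise_sd Per-gene noise standard deviation.
#' @param factor_loading_sd Standard deviation of the gene loadings on the
#'   pair-level latent factor; 0 gives independent genes.
#' @param signal_strata Strata in which signal genes carry their planted
#'   trajectory; default all strata.
#' @param stratum_shift Constant added to signal genes in `signal_strata`
#'   in every period (for strata-difference simulations).
#' @param seed Integer seed; identical configs yield identical datasets.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes, design = uniform_design(),
                              n_signal = 0L, signal_labels = "123",
                              delta = 0, noise_sd = 1,
                              factor_loading_sd = 0, signal_strata = NULL,
                              stratum_shift = 0, seed = 1L) {
  stopifnot(is.data.frame(design),
            all(c("stratum", "time_period", "n_pairs") %in% names(design)))
  if (any(design$n_pairs < 2L))
    stop("every stratum x period cell needs at least 2 pairs", call. = FALSE)
  if (n_signal > n_genes)
    stop("n_signal cannot exceed n_genes", call. = FALSE)
  if (delta < 0) stop("delta must be non-negative", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (factor_loading_sd < 0)
    stop("factor_loading_sd must be non-negative", call. = FALSE)
  n_periods <- max(design$time_period)
  if (!setequal(unique(design$time_period), seq_len(n_periods)))
    stop("design must cover periods 1..T for every stratum", call. = FALSE)
  valid <- enumerate_curve_groups(max(n_periods, 2L))
  if (n_signal > 0L && !all(signal_labels %in% valid))
    stop("invalid signal label(s): ",
         paste(setdiff(signal_labels, valid), collapse = ", "), call. = FALSE)
  if (is.null(signal_strata)) signal_strata <- unique(design$stratum)
  structure(list(n_genes = as.integer(n_genes), design = design,
                 n_signal = as.integer(n_signal),
                 signal_labels = as.character(signal_labels),
                 delta = delta, noise_sd = noise_sd,
                 factor_loading_sd = factor_loading_sd,
                 signal_strata = signal_strata,
                 stratum_shift = stratum_shift, seed = as.integer(seed)),
            class = "simulation_config")
}

# Planted per-period mean for a label: delta * (rank of period t - (T+1)/2).
# The label's digit for period t sits at string position T - t + 1.
.planted_means <- function(label, n_periods, delta) {
  digits <- as.integer(strsplit(label, "")[[1L]])
  rank_of_t <- rev(digits) # element t = rank of period t
  delta * (rank_of_t - (n_periods + 1) / 2)
}

#' Generate a paired log2-difference dataset with planted trajectories
#'
#' @param cfg A [simulation_config()] object.
#' @return List with `x` (genes x pairs matrix), `annotation` (pair
#'   annotation data.frame) and `truth` (data.frame with `gene_id`,
#'   `is_signal`, `label`; planted per-period means of the signal genes in
#'   attribute `"planted_means"`, one row per signal gene, columns t1..tT).
#' @export
generate_dataset <- function(cfg) {
  if (!inherits(cfg, "simulation_config"))
    stop("cfg must be built with simulation_config()", call. = FALSE)
  set.seed(cfg$seed)
  des <- cfg$design
  ann <- data.frame(
    pair_id = sprintf("p%05d", seq_len(sum(des$n_pairs))),
    stratum = rep(des$stratum, des$n_pairs),
    time_period = rep(des$time_period, des$n_pairs),
    stringsAsFactors = FALSE)
  n_periods <- max(ann$time_period)
  G <- cfg$n_genes
  P <- nrow(ann)
  gene_ids <- sprintf("g%05d", seq_len(G))
  labels <- if (cfg$n_signal > 0L)
    rep_len(cfg$signal_labels, cfg$n_signal) else character(0L)

  mu <- matrix(0, G, P)
  planted <- NULL
  if (cfg$n_signal > 0L) {
    planted <- matrix(0, cfg$n_signal, n_periods,
                      dimnames = list(gene_ids[seq_len(cfg$n_signal)],
                                      paste0("t", seq_len(n_periods))))
    in_sig_stratum <- ann$stratum %in% cfg$signal_strata
    for (i in seq_len(cfg$n_signal)) {
      mu_t <- .planted_means(labels[i], n_periods, cfg$delta)
      planted[i, ] <- mu_t
      mu[i, in_sig_stratum] <- mu_t[ann$time_period[in_sig_stratum]] +
        cfg$stratum_shift
    }
  }
  b <- stats::rnorm(G, 0, cfg$factor_loading_sd)
  f <- stats::rnorm(P)
  eps <- matrix(stats::rnorm(G * P, 0, cfg$noise_sd), G, P)
  x <- mu + outer(b, f) + eps
  dimnames(x) <- list(gene_ids, ann$pair_id)
  truth <- data.frame(
    gene_id = gene_ids,
    is_signal = seq_len(G) <= cfg$n_signal,
    label = c(labels, rep(NA_character_, G - cfg$n_signal)),
    stringsAsFactors = FALSE)
  attr(truth, "planted_means") <- planted
  list(x = x, annotation = ann, truth = truth)
}

#' Monte-Carlo type-I error and power estimation
#'
#' Repeatedly generates datasets from each configuration, applies a test and
#' reports the fraction of replicates rejecting at the given level, with its
#' binomial Monte-Carlo standard error `sqrt(r(1-r)/n_reps)`. With `delta = 0`
#' (or no planted difference) this estimates type-I error; otherwise power.
#'
#' @param configs One [simulation_config()] or a list of them. Each
#'   replicate's dataset seed is derived from `seed`, the config index and
#'   the replicate index (the config's own seed is ignored), so every config
#'   in the grid sees the same replicate seed sequence.
#' @param test Either a function `(x, annotation, seed) -> p-value`, or one
#'   of `"trend_global"` (global within-stratum trend test), `"z"`
#'   (curve-group-variable strata test), `"lk"` (L_k strata test).
#' @param n_reps Number of replicates per config.
#' @param level Rejection level; default 0.05.
#' @param seed Master seed.
#' @param test_args Named list of extra arguments for the built-in tests,
#'   e.g. `list(stratum = "S1", alpha = 0.01, n_perm = 199)` for
#'   `"trend_global"`; `list(label = "123", selection_stratum = , strata = ,
#'   m = , n_perm = )` for `"z"`; `list(strata = , k = 100, weights = ,
#'   n_perm = )` for `"lk"`.
#' @return Data.frame with one row per config: `config`, `rejection_rate`,
#'   `se`, `n_reps`, `level`.
#' @export
estimate_error_rates <- function(configs, test, n_reps, level = 0.05,
                                 seed = 1L, test_args = list()) {
  if (inherits(configs, "simulation_config")) configs <- list(configs)
  if (n_reps < 1L) stop("n_reps must be at least 1", call. = FALSE)
  test_fun <- if (is.function(test)) test else .builtin_test(test, test_args)
  rates <- vapply(seq_along(configs), function(ci) {
    cfg <- configs[[ci]]
    reject <- vapply(seq_len(n_reps), function(r) {
      rep_seed <- derive_seed(derive_seed(seed, ci), r)
      cfg_r <- cfg
      cfg_r$seed <- rep_seed
      d <- generate_dataset(cfg_r)
      p <- test_fun(d$x, d$annotation, derive_seed(rep_seed, 1L))
      p <= level
    }, logical(1L))
    mean(reject)
  }, numeric(1L))
  data.frame(config = seq_along(configs), rejection_rate = rates,
             se = sqrt(rates * (1 - rates) / n_reps),
             n_reps = as.integer(n_reps), level = level, row.names = NULL)
}

# Closures wrapping the package's tests as (x, ann, seed) -> p-value.
.builtin_test <- function(name, args) {
  name <- match.arg(name, c("trend_global", "z", "lk"))
  get_arg <- function(key, default) if (!is.null(args[[key]])) args[[key]] else default
  switch(name,
    trend_global = function(x, ann, seed) {
      res <- trend_test_stratum(
        x, ann,
        stratum = get_arg("stratum", ann$stratum[1L]),
        alpha = get_arg("alpha", 0.01),
        n_perm = get_arg("n_perm", 199L), seed = seed)
      res$report$p_value[res$report$label == "global"]
    },
    z = function(x, ann, seed) {
      strata <- get_arg("strata", unique(ann$stratum)[1:2])
      res <- z_strata_test(
        x, ann,
        label = get_arg("label", "123"),
        selection_stratum = get_arg("selection_stratum", strata[1L]),
        strata = strata, scope = get_arg("scope", "all"),
        m = get_arg("m", 100L),
        n_perm = get_arg("n_perm", 199L), seed = seed)
      res$p_value
    },
    lk = function(x, ann, seed) {
      strata <- get_arg("strata", unique(ann$stratum)[1:2])
      res <- lk_test(
        x, ann, strata = strata,
        weights = get_arg("weights", "equal"),
        k_grid = get_arg("k", 100L),
        scope = get_arg("scope", "all"),
        n_perm = get_arg("n_perm", 199L), seed = seed)
      res$table$p_value[1L]
    })
}
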