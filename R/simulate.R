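#' Configuration of a FWER/power simulation study
#'
#' Describes one simulation condition: the data-generating family, whether
#' the two groups share covariance parameters, the design sizes, the effect
#' size, and the Monte-Carlo scale. Defaults reproduce the reference study
#' design: per-gene SDs drawn from \{0.1, 0.5, 1, 1.25, 1.5\}, per-subset
#' intraclass correlations from \{0, 0.25, 0.5, 0.75, 0.9\}, subsets per set
#' uniform on 5..16, genes per subset uniform on 5..10, mixture weight 0.2,
#' chi-square dfs \{4,5\} (numerator, per gene) and \{1,2\} (shared
#' denominator, per subset), 1000 runs and 5000 bootstrap replicates.
#'
#' @param family `"normal"`, `"lognormal"`, `"beta"`, or `"mixture"`.
#' @param variance_mode `"homoscedastic"` (both groups share the sigma/rho
#'   draws) or `"heteroscedastic"` (independent draws). The log-normal
#'   family is homoscedastic only; for the mixture family the mode refers
#'   to the two mixture components. The beta family's dispersion is fixed
#'   by its df draws, always shared between groups.
#' @param K number of gene sets (5 or 10 in the reference design).
#' @param n per-group sample size.
#' @param delta treatment mean shift applied to every gene (0 = null/FWER
#'   mode; on the log scale for the log-normal family; unsupported for the
#'   beta family, whose means are fixed by its dfs).
#' @param subsets_per_set inclusive integer range for m_k.
#' @param genes_per_subset inclusive integer range for subset sizes (set
#'   both ends to 20 for the fixed-size diagonal-vs-full comparison).
#' @param sigma_pool,rho_pool,mix_weight,chisq_df_U_pool,chisq_df_V_pool
#'   generator parameter pools (see above).
#' @param runs number of simulation runs R.
#' @param bootstraps bootstrap replicates B per run.
#' @param alpha test level.
#' @param statistic `"diag"` or `"full"` subset statistic.
#' @param seed master seed; every run's structure, data and bootstrap
#'   resamples derive from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(family = c("normal", "lognormal", "beta",
                                         "mixture"),
                              variance_mode = c("homoscedastic",
                                                "heteroscedastic"),
                              K = 5, n = 40, delta = 0,
                              subsets_per_set = c(5, 16),
                              genes_per_subset = c(5, 10),
                              sigma_pool = c(0.1, 0.5, 1, 1.25, 1.5),
                              rho_pool = c(0, 0.25, 0.5, 0.75, 0.9),
                              mix_weight = 0.2,
                              chisq_df_U_pool = c(4, 5),
                              chisq_df_V_pool = c(1, 2),
                              runs = 1000, bootstraps = 5000,
                              alpha = 0.05,
                              statistic = c("diag", "full"),
                              seed = 1) {
  family <- match.arg(family)
  variance_mode <- match.arg(variance_mode)
  statistic <- match.arg(statistic)
  if (family == "lognormal" && variance_mode == "heteroscedastic")
    stop("the log-normal family is defined with equal covariance matrices ",
         "(homoscedastic only)")
  if (family == "beta" && delta != 0)
    stop("the beta family has no mean-shift parameter; use delta = 0")
  stopifnot(K >= 1, n >= 2, delta >= 0, runs >= 1, bootstraps >= 1,
            alpha >= 0, alpha < 1,
            length(subsets_per_set) == 2, subsets_per_set[1] >= 1,
            diff(subsets_per_set) >= 0,
            length(genes_per_subset) == 2, genes_per_subset[1] >= 1,
            diff(genes_per_subset) >= 0,
            mix_weight > 0, mix_weight < 1,
            all(sigma_pool > 0), all(rho_pool >= 0), all(rho_pool < 1))
  structure(list(family = family, variance_mode = variance_mode,
                 K = as.integer(K), n = as.integer(n), delta = delta,
                 subsets_per_set = as.integer(subsets_per_set),
                 genes_per_subset = as.integer(genes_per_subset),
                 sigma_pool = sigma_pool, rho_pool = rho_pool,
                 mix_weight = mix_weight,
                 chisq_df_U_pool = as.integer(chisq_df_U_pool),
                 chisq_df_V_pool = as.integer(chisq_df_V_pool),
                 runs = as.integer(runs),
                 bootstraps = as.integer(bootstraps),
                 alpha = alpha, statistic = statistic,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# sample() treats a length-1 numeric pool as 1:n; always index the pool.
draw_pool <- function(pool, k) pool[sample.int(length(pool), k,
                                               replace = TRUE)]

draw_range <- function(k, range) {
  if (range[1] == range[2]) rep(range[1], k)
  else draw_pool(seq(range[1], range[2]), k)
}

#' Draw one realized set/subset structure and its generator parameters
#'
#' Realizes the random design for one simulation run: the number of subsets
#' per set, the subset sizes, the disjoint gene blocks, and the per-gene /
#' per-subset generator parameters (SDs and correlations for the normal
#' families, chi-square dfs for the beta family, per-component parameters
#' for the mixture). In homoscedastic mode the two groups (components)
#' share the same draws; in heteroscedastic mode they draw independently.
#'
#' @param config a [simulation_config()].
#' @param run_seed integer seed for this run's draws.
#' @return list of class `sim_structure`: `K`, `m`, `set_of_subset`,
#'   `sizes`, `blocks` (gene index vector per flat subset),
#'   `subset_of_gene`, `G`, `gene_ids`, and per-group (or per-component)
#'   parameter lists.
#' @export
sample_hierarchy_structure <- function(config, run_seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(run_seed)
  m <- draw_range(config$K, config$subsets_per_set)
  n_subsets <- sum(m)
  sizes <- draw_range(n_subsets, config$genes_per_subset)
  ends <- cumsum(sizes)
  blocks <- mapply(function(a, b) seq.int(a, b), c(1L, ends[-n_subsets] + 1L),
                   ends, SIMPLIFY = FALSE)
  G <- ends[n_subsets]
  subset_of_gene <- rep.int(seq_len(n_subsets), sizes)
  st <- list(K = config$K, m = m, set_of_subset = rep.int(seq_len(config$K), m),
             sizes = sizes, blocks = blocks, subset_of_gene = subset_of_gene,
             G = G, gene_ids = sprintf("g%05d", seq_len(G)),
             family = config$family, variance_mode = config$variance_mode,
             mix_weight = config$mix_weight)

  draw_sigrho <- function() list(
    sigma = draw_pool(config$sigma_pool, G),
    rho = draw_pool(config$rho_pool, n_subsets))

  if (config$family %in% c("normal", "lognormal")) {
    g1 <- draw_sigrho()
    g2 <- if (config$variance_mode == "heteroscedastic") draw_sigrho() else g1
    st$groups <- list(g1, g2)
  } else if (config$family == "mixture") {
    c1 <- draw_sigrho()
    c2 <- if (config$variance_mode == "heteroscedastic") draw_sigrho() else c1
    st$components <- list(c1, c2)
  } else {                          # beta: df draws always shared
    st$df_U <- draw_pool(config$chisq_df_U_pool, G)
    st$df_V <- draw_pool(config$chisq_df_V_pool, n_subsets)
  }
  class(st) <- "sim_structure"
  st
}

# Standardized intraclass draws: G x n matrix with unit variance and
# within-subset correlation rho (constant per subset block), independent
# across blocks. Shared factor construction: sqrt(rho) z0 + sqrt(1-rho) z.
intraclass_std <- function(structure, n, rho_by_subset) {
  G <- structure$G
  n_subsets <- length(structure$sizes)
  z0 <- matrix(stats::rnorm(n_subsets * n), n_subsets, n)
  z <- matrix(stats::rnorm(G * n), G, n)
  r <- rho_by_subset[structure$subset_of_gene]
  sqrt(r) * z0[structure$subset_of_gene, , drop = FALSE] +
    sqrt(1 - r) * z
}

#' Generate intraclass-correlated multivariate normal expression data
#'
#' Each subset block is multivariate normal with per-gene SDs and a
#' constant within-block correlation taken from the structure's draws for
#' the requested group; blocks are independent. Control group mean is 0 for
#' every gene, treatment mean is `delta`.
#'
#' @param structure a `sim_structure` from [sample_hierarchy_structure()]
#'   (normal or lognormal family).
#' @param n number of samples.
#' @param delta mean shift (0 for control).
#' @param group_index 1 or 2 (selects the group's sigma/rho draws).
#' @return numeric G x n matrix with the structure's gene ids as row names.
#' @export
gen_mvn_intraclass <- function(structure, n, delta, group_index) {
  stopifnot(inherits(structure, "sim_structure"), n >= 2,
            group_index %in% 1:2,
            structure$family %in% c("normal", "lognormal"))
  par <- structure$groups[[group_index]]
  y <- intraclass_std(structure, n, par$rho)
  x <- delta + par$sigma * y
  rownames(x) <- structure$gene_ids
  x
}

#' Generate multivariate log-normal expression data
#'
#' Exponentiates an intraclass multivariate normal draw with equal
#' covariance matrices in both groups; `delta` shifts the log-scale mean of
#' the treatment group.
#'
#' @inheritParams gen_mvn_intraclass
#' @export
gen_lognormal <- function(structure, n, delta, group_index) {
  if (structure$variance_mode != "homoscedastic")
    stop("the log-normal family is homoscedastic only")
  exp(gen_mvn_intraclass(structure, n, delta, group_index))
}

#' Generate multivariate beta (chi-square ratio) methylation-like data
#'
#' Per subset block and per sample, draws independent numerators
#' U_g ~ chi-square(a_g) (a_g in \{4,5\}, per gene) and one shared
#' denominator component V ~ chi-square(b) (b in \{1,2\}, per subset), and
#' emits Z_g = U_g / (U_g + V). Marginally Z_g ~ Beta(a_g/2, b/2) — mean
#' a_g/(a_g+b), between 4/6 and 5/6 for the default pools — and the shared
#' V induces positive dependence within the block. Both groups use the same
#' df draws, so the two groups are identically distributed (null).
#'
#' @inheritParams gen_mvn_intraclass
#' @export
gen_multivariate_beta <- function(structure, n, group_index) {
  stopifnot(inherits(structure, "sim_structure"), n >= 2,
            structure$family == "beta")
  G <- structure$G
  n_subsets <- length(structure$sizes)
  u <- matrix(stats::rchisq(G * n, df = rep(structure$df_U, times = n)),
              G, n)
  v <- matrix(stats::rchisq(n_subsets * n,
                            df = rep(structure$df_V, times = n)),
              n_subsets, n)
  z <- u / (u + v[structure$subset_of_gene, , drop = FALSE])
  rownames(z) <- structure$gene_ids
  z
}

#' Generate two-component normal mixture expression data
#'
#' Each sample vector is drawn whole from N(0, Sigma_1) with probability
#' `mix_weight` (default 0.2) and from N(1, Sigma_2) otherwise; the Sigmas
#' follow the intraclass construction (identical in homoscedastic mode,
#' independent sigma/rho draws per component otherwise). Both groups use
#' the same mixture; `delta` shifts every treatment mean.
#'
#' @inheritParams gen_mvn_intraclass
#' @export
gen_mixture_normal <- function(structure, n, group_index, delta = 0) {
  stopifnot(inherits(structure, "sim_structure"), n >= 2,
            structure$family == "mixture")
  lab <- stats::runif(n) < structure$mix_weight   # TRUE -> component 1
  c1 <- structure$components[[1]]
  c2 <- structure$components[[2]]
  y1 <- c1$sigma * intraclass_std(structure, n, c1$rho)
  y2 <- 1 + c2$sigma * intraclass_std(structure, n, c2$rho)
  x <- delta + ifelse(matrix(lab, structure$G, n, byrow = TRUE), y1, y2)
  rownames(x) <- structure$gene_ids
  x
}

# One group's data matrix under the configured family.
generate_group <- function(structure, config, n, delta, group_index) {
  switch(config$family,
         normal = gen_mvn_intraclass(structure, n, delta, group_index),
         lognormal = gen_lognormal(structure, n, delta, group_index),
         beta = gen_multivariate_beta(structure, n, group_index),
         mixture = gen_mixture_normal(structure, n, group_index,
                                      delta = delta))
}

# Hierarchy object matching a realized structure (disjoint gene blocks).
structure_hierarchy <- function(structure) {
  flat <- split(seq_along(structure$sizes), structure$set_of_subset)
  sets <- lapply(seq_len(structure$K), function(k) {
    subs <- lapply(flat[[k]], function(s)
      structure$gene_ids[structure$blocks[[s]]])
    names(subs) <- paste0("subset", seq_along(subs))
    subs
  })
  names(sets) <- paste0("set", seq_len(structure$K))
  gene_set_hierarchy(sets)
}

#' Estimate the FWER or power of the full procedure by simulation
#'
#' For each of R runs: redraw the set/subset structure and generator
#' parameters, generate control and treatment groups (treatment mean
#' shifted by `delta` on every gene), run the complete pipeline
#' (subset statistics, residual-bootstrap p-values with B replicates,
#' two-level Bonferroni at `alpha`), and record whether at least one
#' rejection occurred anywhere. With `delta = 0` the rejection proportion
#' estimates the family-wise error rate; with `delta > 0` it estimates
#' power (the probability of rejecting at least one false null).
#'
#' @param config a [simulation_config()].
#' @param progress print a dot every 50 runs (default `FALSE`).
#' @return list of class `sim_result`: `rate`, `se` (binomial standard
#'   error), `rejected` (logical per run), and the `config`.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  R <- config$runs
  set.seed(config$seed)
  run_seeds <- matrix(sample.int(2147483646L, 2L * R), nrow = 2L)
  rejected <- logical(R)
  for (r in seq_len(R)) {
    st <- sample_hierarchy_structure(config, run_seeds[1L, r])
    x1 <- generate_group(st, config, config$n, 0, 1L)
    x2 <- generate_group(st, config, config$n, config$delta, 2L)
    mat <- cbind(x1, x2)
    colnames(mat) <- sprintf("s%04d", seq_len(ncol(mat)))
    study <- expression_study(mat, group = rep(1:2, each = config$n))
    res <- gsa_test(study, structure_hierarchy(st),
                    alpha = config$alpha, B = config$bootstraps,
                    seed = run_seeds[2L, r], statistic = config$statistic)
    rejected[r] <- any(res$sets$significant)
    if (progress && r %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  rate <- mean(rejected)
  structure(list(rate = rate, se = sqrt(rate * (1 - rate) / R),
                 rejected = rejected, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  kind <- if (x$config$delta == 0) "FWER" else "power"
  cat(sprintf("%s estimate: %.4f (SE %.4f; R = %d, B = %d, %s %s, n = %d, K = %d, delta = %g)\n",
              kind, x$rate, x$se, x$config$runs, x$config$bootstraps,
              x$config$family, x$config$variance_mode, x$config$n,
              x$config$K, x$config$delta))
  invisible(x)
}

#' Compare the diagonal and full-covariance statistics on paired seeds
#'
#' Runs the simulation study twice with identical master seeds — once with
#' the diagonal statistic and once with the full-covariance statistic — on
#' fixed-size subsets, so both statistics see exactly the same data and
#' resamples. The per-group sample size must exceed the subset size or the
#' full-covariance statistic is undefined.
#'
#' @param config a [simulation_config()] whose `genes_per_subset` range is
#'   degenerate (a fixed subset size, e.g. `c(20, 20)`).
#' @return list with elements `diag` and `full`, each a `sim_result`.
#' @export
run_table3_comparison <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$genes_per_subset[1] != config$genes_per_subset[2])
    stop("the comparison uses a fixed subset size; set both ends of ",
         "`genes_per_subset` to the same value")
  if (config$n <= config$genes_per_subset[1])
    stop("the full-covariance statistic needs n > subset size (n = ",
         config$n, ", subset size = ", config$genes_per_subset[1], ")")
  cfg_diag <- config; cfg_diag$statistic <- "diag"
  cfg_full <- config; cfg_full$statistic <- "full"
  list(diag = run_study(cfg_diag), full = run_study(cfg_full))
}
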