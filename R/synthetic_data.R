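#' Write a simulation ground-truth object as JSON
#'
#' Named numeric vectors (e.g. planted fold changes) are written as JSON
#' objects so that names survive a round trip through
#' [jsonlite::read_json()].
#'
#' @param truth Ground-truth list from a generator.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  enc <- rapply(truth, function(x) {
    if (!is.null(names(x))) as.list(x) else x
  }, how = "replace")
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Default synthetic lectin panel
#'
#' A 37-lectin panel: the 14 lectins with published fold changes in the VPA
#' rat study, with base intensities proportional to their published control
#' NFIs, plus 23 synthetic filler lectins sharing the remaining block mass
#' so that block sums behave like a real panel.
#'
#' @param scale Total base intensity of a block.
#' @return Named numeric vector of base intensities.
#' @export
default_lectin_panel <- function(scale = 10000) {
  printed <- c(ConA = 0.109, GNA = 0.020, "GSL-II" = 0.059, "PHA-E" = 0.031,
               DSA = 0.027, WGA = 0.083, "PTL-I" = 0.042, DBA = 0.006,
               VVA = 0.071, ECA = 0.054, Jacalin = 0.102, "MAL-I" = 0.024,
               BPL = 0.049, RCA120 = 0.024)
  fillers <- stats::setNames(rep((1 - sum(printed)) / 23, 23),
                             sprintf("FILL%02d", seq_len(23)))
  c(printed, fillers) * scale
}

#' Simulate spot-level lectin-microarray slides with known truth
#'
#' Spot foregrounds are an additive background plus a lectin base intensity
#' scaled by the group multiplier and multiplicative lognormal noise with
#' coefficient of variation `spot_cv`; the background channel is Gaussian
#' around `bg_mean`. Fold changes are planted on the compositional (NFI)
#' scale: case-group intensities of unplanted lectins are rescaled by a
#' common factor so the block total is preserved, which makes the planted
#' NFI fold changes exact in the noiseless limit. A fraction `dim_frac` of
#' spots can be dimmed to background level to exercise the detection
#' filter.
#'
#' @param panel Named vector of base intensities (default
#'   [default_lectin_panel()]).
#' @param n_samples Samples per group.
#' @param n_slides Replicate slides per sample (default 3, each with one
#'   block of triplicate spots per lectin).
#' @param n_replicates Spots per lectin per block (default 3).
#' @param planted_fc Named vector of signed fold changes (case vs control)
#'   for a subset of panel lectins.
#' @param spot_cv Multiplicative spot coefficient of variation (>= 0).
#' @param bg_mean,bg_sd Background mean and SD (fluorescence units).
#' @param dim_frac Fraction of spots planted as dim (signal suppressed).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return List with `spots` (data.frame in [read_spot_tsv()] layout) and
#'   `truth` (list: `planted_fc`, `filler_fc`, `dim_spots` row indices,
#'   `seed`, and the generator parameters).
#' @export
simulate_lectin_slides <- function(panel = default_lectin_panel(),
                                   n_samples = 3, n_slides = 3,
                                   n_replicates = 3,
                                   planted_fc = numeric(0),
                                   spot_cv = 0.1,
                                   bg_mean = 100, bg_sd = 10,
                                   dim_frac = 0, seed = 1) {
  if (spot_cv < 0) stop("spot_cv must be non-negative")
  if (bg_mean <= 0 || bg_sd < 0) stop("background parameters must be positive")
  if (dim_frac < 0 || dim_frac >= 1) stop("dim_frac must lie in [0, 1)")
  if (length(planted_fc) > 0) {
    if (is.null(names(planted_fc)) || !all(names(planted_fc) %in% names(panel))) {
      stop("planted_fc must be named by panel lectins")
    }
    if (any(abs(planted_fc) < 1)) stop("planted fold changes must satisfy |fc| >= 1")
  }

  ratio <- function(fc) ifelse(fc >= 1, fc, -1 / fc)
  mult <- stats::setNames(rep(1, length(panel)), names(panel))
  gamma <- 1
  if (length(planted_fc) > 0) {
    r <- ratio(planted_fc)
    mult[names(planted_fc)] <- r
    planted_mass <- sum(panel[names(planted_fc)])
    total <- sum(panel)
    gamma <- (total - sum(panel[names(planted_fc)] * r)) /
      (total - planted_mass)
    if (!is.finite(gamma) || gamma <= 0) {
      stop("planted fold changes leave no mass for unplanted lectins")
    }
    unplanted <- setdiff(names(panel), names(planted_fc))
    mult[unplanted] <- gamma
  }

  sdlog <- if (spot_cv > 0) sqrt(log(1 + spot_cv^2)) else 0

  withr_seed <- function(expr) { set.seed(seed); expr }
  spots <- withr_seed({
    rows <- expand.grid(replicate = seq_len(n_replicates),
                        lectin = names(panel),
                        slide = seq_len(n_slides),
                        sample = seq_len(n_samples),
                        group = c("control", "case"),
                        stringsAsFactors = FALSE)
    n <- nrow(rows)
    base <- panel[rows$lectin]
    m <- ifelse(rows$group == "case", mult[rows$lectin], 1)
    noise <- if (sdlog > 0) exp(stats::rnorm(n, -sdlog^2 / 2, sdlog)) else 1
    signal <- base * m * noise
    dim_idx <- integer(0)
    if (dim_frac > 0) {
      dim_idx <- which(stats::runif(n) < dim_frac)
      signal[dim_idx] <- 0
    }
    bg_channel <- pmax(stats::rnorm(n, bg_mean, bg_sd), 0)
    df <- data.frame(
      slide_id = sprintf("%s_s%d_r%d", rows$group, rows$sample, rows$slide),
      sample_id = sprintf("%s_s%d", rows$group, rows$sample),
      group = rows$group,
      block = 1L,
      lectin = rows$lectin,
      replicate = rows$replicate,
      foreground = bg_mean + signal,
      background = bg_channel,
      stringsAsFactors = FALSE)
    attr(df, "dim_idx") <- dim_idx
    df
  })
  truth <- list(planted_fc = planted_fc,
                filler_fc = if (gamma >= 1) gamma else -1 / gamma,
                dim_spots = attr(spots, "dim_idx"),
                seed = seed,
                params = list(n_samples = n_samples, n_slides = n_slides,
                              n_replicates = n_replicates, spot_cv = spot_cv,
                              bg_mean = bg_mean, bg_sd = bg_sd,
                              dim_frac = dim_frac))
  attr(spots, "dim_idx") <- NULL
  list(spots = spots, truth = truth)
}

#' Simulate a two-group negative-binomial count matrix with planted effects
#'
#' Counts are negative-binomial with gene baseline means drawn lognormally;
#' a planted gene's mean is multiplied by `2^(+log2fc/2)` in the case group
#' and `2^(-log2fc/2)` in the control group (the effect is split so the
#' average expression is preserved). Library-size factors scale all means
#' of a sample.
#'
#' @param n_genes Number of genes; gene ids are `g1..gN` unless
#'   `gene_ids` is given.
#' @param n_per_group Samples per group (default 3).
#' @param planted Named numeric vector: gene id -> log2 fold change.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the gene
#'   baseline means.
#' @param lib_sizes Optional vector of 2*`n_per_group` library factors
#'   (default all 1).
#' @param gene_ids Optional explicit gene ids.
#' @param seed Integer seed.
#' @return List with `counts` (matrix genes x samples), `groups`
#'   (character vector), and `truth` (list with `planted`, `baseline`,
#'   `seed`).
#' @export
simulate_counts <- function(n_genes = 2000, n_per_group = 3,
                            planted = numeric(0), dispersion = 0.05,
                            baseline_meanlog = log(200), baseline_sdlog = 1,
                            lib_sizes = NULL, gene_ids = NULL, seed = 1) {
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (n_per_group < 2) stop("at least 2 samples per group are required")
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(n_genes))
  if (length(gene_ids) != n_genes) stop("gene_ids must have length n_genes")
  if (length(planted) > 0 &&
      (is.null(names(planted)) || !all(names(planted) %in% gene_ids))) {
    stop("planted genes must be named by gene ids in the universe")
  }
  if (is.null(lib_sizes)) lib_sizes <- rep(1, 2 * n_per_group)
  if (length(lib_sizes) != 2 * n_per_group) {
    stop("lib_sizes must have one factor per sample")
  }

  set.seed(seed)
  baseline <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  names(baseline) <- gene_ids
  lfc <- stats::setNames(rep(0, n_genes), gene_ids)
  lfc[names(planted)] <- planted
  groups <- rep(c("control", "case"), each = n_per_group)
  mu <- outer(baseline, rep(1, 2 * n_per_group))
  mu <- mu * 2^(outer(lfc, ifelse(groups == "case", 0.5, -0.5)))
  mu <- sweep(mu, 2, lib_sizes, "*")
  counts <- matrix(
    if (dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    } else {
      stats::rpois(length(mu), lambda = mu)
    },
    nrow = n_genes,
    dimnames = list(gene_ids,
                    sprintf("%s_%d", groups, rep(seq_len(n_per_group), 2))))
  list(counts = counts, groups = groups,
       truth = list(planted = planted, baseline = baseline,
                    dispersion = dispersion, lib_sizes = lib_sizes,
                    seed = seed))
}

#' Simulate a two-group behavioral trial table
#'
#' Durations are normal draws truncated at zero.
#'
#' @param n_a,n_b Animals in the control and case groups (positive).
#' @param means,sds Named lists with per-group numeric vectors
#'   `c(time_stranger=, time_empty=, grooming=)`; elements `a` (control)
#'   and `b` (case).
#' @param seed Integer seed.
#' @return data.frame `animal_id`, `group`, `time_stranger`, `time_empty`,
#'   `grooming`, `si`.
#' @export
simulate_behavior <- function(n_a = 8, n_b = 11,
                              means = list(a = c(time_stranger = 300,
                                                 time_empty = 150,
                                                 grooming = 49),
                                           b = c(time_stranger = 220,
                                                 time_empty = 233,
                                                 grooming = 127)),
                              sds = list(a = c(time_stranger = 40,
                                               time_empty = 30,
                                               grooming = 13),
                                         b = c(time_stranger = 37,
                                               time_empty = 23,
                                               grooming = 37)),
                              seed = 1) {
  if (n_a <= 0 || n_b <= 0) stop("group sizes must be positive")
  if (any(unlist(sds) < 0)) stop("standard deviations must be non-negative")
  set.seed(seed)
  draw <- function(n, m, s) pmax(stats::rnorm(n, m, s), 0)
  mk <- function(n, group, m, s) {
    data.frame(animal_id = sprintf("%s_%02d", group, seq_len(n)),
               group = group,
               time_stranger = draw(n, m[["time_stranger"]], s[["time_stranger"]]),
               time_empty = draw(n, m[["time_empty"]], s[["time_empty"]]),
               grooming = draw(n, m[["grooming"]], s[["grooming"]]),
               stringsAsFactors = FALSE)
  }
  df <- rbind(mk(n_a, "control", means$a, sds$a),
              mk(n_b, "case", means$b, sds$b))
  df$si <- sociability_index(df$time_stranger, df$time_empty)
  rownames(df) <- NULL
  df
}

#' Simulate a modular confidence-weighted network
#'
#' Builds complete within-module graphs at weight `within_w` and sparse
#' between-module edges at weight `between_w`.
#'
#' @param modules List of node-name vectors, or integer vector of module
#'   sizes (nodes are then auto-named `m<i>_n<j>`).
#' @param within_w,between_w Edge confidences in (0, 1].
#' @param p_between Probability of each possible between-module edge.
#' @param seed Integer seed.
#' @return List with `edges` (data.frame `node_a`, `node_b`, `confidence`)
#'   and `truth` (module membership).
#' @export
simulate_network <- function(modules = c(5, 5), within_w = 0.8,
                             between_w = 0.3, p_between = 0.3, seed = 1) {
  if (within_w <= 0 || within_w > 1 || between_w <= 0 || between_w > 1) {
    stop("edge weights must lie in (0, 1]")
  }
  if (is.numeric(modules) && !is.list(modules)) {
    if (any(modules <= 0)) stop("module sizes must be positive")
    modules <- lapply(seq_along(modules), function(i) {
      sprintf("m%d_n%d", i, seq_len(modules[i]))
    })
  }
  set.seed(seed)
  edges <- list()
  for (m in modules) {
    if (length(m) > 1) {
      pairs <- utils::combn(m, 2)
      edges[[length(edges) + 1L]] <- data.frame(node_a = pairs[1, ],
                                                node_b = pairs[2, ],
                                                confidence = within_w,
                                                stringsAsFactors = FALSE)
    }
  }
  nm <- length(modules)
  if (nm > 1) {
    for (i in seq_len(nm - 1)) {
      for (j in seq((i + 1), nm)) {
        grid <- expand.grid(a = modules[[i]], b = modules[[j]],
                            stringsAsFactors = FALSE)
        pick <- stats::runif(nrow(grid)) < p_between
        if (any(pick)) {
          edges[[length(edges) + 1L]] <- data.frame(
            node_a = grid$a[pick], node_b = grid$b[pick],
            confidence = between_w, stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(node_a = character(0), node_b = character(0),
               confidence = numeric(0))
  membership <- stats::setNames(
    rep(seq_along(modules), lengths(modules)), unlist(modules))
  list(edges = edges, truth = list(membership = membership, seed = seed))
}
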