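#' Read a spot-level lectin microarray table
#'
#' Expects a TSV with header and columns `slide_id`, `sample_id`, `group`,
#' `block`, `lectin`, `replicate`, `foreground`, `background`.
#'
#' @param path Path to the TSV file.
#' @return data.frame of spot measurements.
#' @export
read_spot_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  required <- c("slide_id", "sample_id", "group", "block", "lectin",
                "replicate", "foreground", "background")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("spot table is missing column(s): ", paste(missing, collapse = ", "))
  }
  validate_spots(df)
  df
}

validate_spots <- function(spots) {
  if (any(!is.finite(spots$foreground)) || any(!is.finite(spots$background))) {
    stop("foreground and background intensities must be finite")
  }
  if (any(spots$foreground < 0) || any(spots$background < 0)) {
    stop("foreground and background intensities must be non-negative")
  }
  key <- paste(spots$slide_id, spots$block, spots$lectin, spots$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (slide, block, lectin, replicate) spot: ",
         key[duplicated(key)][1])
  }
  invisible(spots)
}

#' Read a GenePix-results (GPR dialect) file as spot measurements
#'
#' Parses the tab-separated GenePix Results layout: an ATF preamble
#' (`ATF <version>` line, a line giving the number of optional header
#' records, then that many header lines) followed by a tabular section.
#' Columns `Block`, `Name`, `F635 Median` and `B635 Median` are mapped to
#' `block`, `lectin`, `foreground` and `background`. Replicate indices are
#' assigned within each (block, lectin) in file order.
#'
#' @param path Path to the GPR file.
#' @param slide_id,sample_id,group Identity of the slide; GPR files carry a
#'   single slide with no sample/group metadata.
#' @return data.frame in the same layout as [read_spot_tsv()].
#' @export
read_gpr <- function(path, slide_id, sample_id, group) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || !grepl("^ATF", lines[1])) {
    stop("not an ATF/GPR file: ", path)
  }
  n_header <- as.integer(strsplit(trimws(lines[2]), "\t|\\s+")[[1]][1])
  tab <- utils::read.delim(text = paste(lines[-seq_len(2 + n_header)],
                                        collapse = "\n"),
                           header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"")
  for (col in c("Block", "Name", "F635 Median", "B635 Median")) {
    if (!(col %in% names(tab))) stop("GPR file lacks column ", shQuote(col))
  }
  df <- data.frame(slide_id = slide_id, sample_id = sample_id, group = group,
                   block = as.integer(tab$Block),
                   lectin = as.character(tab$Name),
                   foreground = as.numeric(tab[["F635 Median"]]),
                   background = as.numeric(tab[["B635 Median"]]),
                   stringsAsFactors = FALSE)
  df$replicate <- stats::ave(seq_len(nrow(df)),
                             paste(df$block, df$lectin), FUN = seq_along)
  df <- df[c("slide_id", "sample_id", "group", "block", "lectin",
             "replicate", "foreground", "background")]
  validate_spots(df)
  df
}

#' Background statistics for one block
#'
#' @param background Numeric vector of local-background intensities of all
#'   spots in a block.
#' @return List with `mean_bg` and `sd_bg`.
#' @export
block_background_stats <- function(background) {
  if (length(background) == 0) stop("no background values")
  sd_bg <- if (length(background) > 1) stats::sd(background) else 0
  list(mean_bg = mean(background), sd_bg = sd_bg)
}

#' Filter effective spots by the detection floor and subtract background
#'
#' A spot is effective when its foreground intensity reaches the detection
#' floor `mean_bg + 2 * sd_bg` (equality survives); effective values are
#' background-subtracted foregrounds (`foreground - mean_bg`). Spots below
#' the floor are discarded as indistinguishable from background.
#'
#' @param spots data.frame of spot measurements for one block (columns
#'   `lectin`, `foreground` required).
#' @param bg Background stats from [block_background_stats()]; computed
#'   from `spots$background` when omitted.
#' @return List with `effective` (data.frame `lectin`, `value`),
#'   `below_detection` (lectins whose spots were all removed), and
#'   `n_removed`.
#' @export
filter_effective_spots <- function(spots, bg = NULL) {
  if (nrow(spots) == 0) stop("at least one spot is required per block")
  if (is.null(bg)) bg <- block_background_stats(spots$background)
  floor <- bg$mean_bg + 2 * bg$sd_bg
  keep <- spots$foreground >= floor
  effective <- data.frame(lectin = spots$lectin[keep],
                          value = spots$foreground[keep] - bg$mean_bg,
                          stringsAsFactors = FALSE)
  below <- setdiff(unique(spots$lectin), unique(effective$lectin))
  list(effective = effective, below_detection = below,
       n_removed = sum(!keep))
}

#' Median-ratio normalization of one block
#'
#' The per-lectin median of effective (background-subtracted) spot values is
#' divided by the sum of the medians of all lectins present in the block, so
#' that the resulting normalized fluorescence intensities (NFIs) of a block
#' sum to 1. Lectins flagged below detection do not enter the denominator.
#'
#' @param effective data.frame with columns `lectin` and `value` (effective
#'   spot values for one block).
#' @return Named numeric vector of NFIs (one per lectin, summing to 1).
#' @export
normalize_block <- function(effective) {
  if (nrow(effective) == 0) stop("empty block")
  med <- tapply(effective$value, effective$lectin, stats::median)
  total <- sum(med)
  if (!(total > 0)) stop("empty block")
  nfi <- stats::setNames(as.numeric(med / total), names(med))
  nfi[order(names(nfi))]
}

#' Process spot measurements into per-slide lectin profiles
#'
#' Applies [filter_effective_spots()] and [normalize_block()] to every block
#' of every slide; when a slide has several blocks its NFI is the mean of
#' its block NFIs per lectin.
#'
#' @param spots data.frame of spot measurements (see [read_spot_tsv()]).
#' @return data.frame with one row per (slide, lectin): `slide_id`,
#'   `sample_id`, `group`, `lectin`, `nfi`.
#' @export
spot_profiles <- function(spots) {
  validate_spots(spots)
  out <- list()
  for (sl in unique(spots$slide_id)) {
    slide <- spots[spots$slide_id == sl, , drop = FALSE]
    block_nfi <- list()
    for (b in unique(slide$block)) {
      blk <- slide[slide$block == b, , drop = FALSE]
      eff <- filter_effective_spots(blk)
      block_nfi[[as.character(b)]] <- normalize_block(eff$effective)
    }
    lectins <- sort(unique(unlist(lapply(block_nfi, names))))
    m <- vapply(block_nfi, function(v) v[lectins], numeric(length(lectins)))
    m <- matrix(m, nrow = length(lectins),
                dimnames = list(lectins, names(block_nfi)))
    nfi <- rowMeans(m, na.rm = TRUE)
    nfi[is.nan(nfi)] <- NA_real_
    out[[length(out) + 1L]] <- data.frame(
      slide_id = sl, sample_id = slide$sample_id[1], group = slide$group[1],
      lectin = lectins, nfi = unname(nfi), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate replicate slides into sample and group NFIs
#'
#' Per-sample NFI is the arithmetic mean of that sample's slide NFIs per
#' lectin; group NFI is the arithmetic mean over samples. A lectin missing
#' (below detection) on a slide is missing for that slide only; a lectin
#' missing in every slide of every sample of a group yields `NA` for that
#' group with a warning.
#'
#' @param profiles data.frame from [spot_profiles()].
#' @return List with `sample_nfi` (data.frame `sample_id`, `group`,
#'   `lectin`, `nfi`) and `group_nfi` (data.frame `group`, `lectin`, `nfi`).
#' @export
aggregate_sample <- function(profiles) {
  sm <- stats::aggregate(list(nfi = profiles$nfi),
                         by = list(sample_id = profiles$sample_id,
                                   group = profiles$group,
                                   lectin = profiles$lectin),
                         FUN = function(x) mean(x, na.rm = TRUE))
  sm$nfi[is.nan(sm$nfi)] <- NA_real_
  gm <- stats::aggregate(list(nfi = sm$nfi),
                         by = list(group = sm$group, lectin = sm$lectin),
                         FUN = function(x) mean(x, na.rm = TRUE))
  gm$nfi[is.nan(gm$nfi)] <- NA_real_
  if (any(is.na(gm$nfi))) {
    miss <- unique(gm$lectin[is.na(gm$nfi)])
    warning("lectin(s) below detection in an entire group, excluded from fold change: ",
            paste(miss, collapse = ", "))
  }
  list(sample_nfi = sm[order(sm$sample_id, sm$lectin), ],
       group_nfi = gm[order(gm$group, gm$lectin), ])
}

#' Signed fold change between two positive intensities
#'
#' Uses the signed ratio convention: `case/control` when the ratio is at
#' least 1, otherwise the negative reciprocal `-control/case`, so that no
#' value falls strictly between -1 and 1 and `fc(a, a) = 1`.
#'
#' @param nfi_control,nfi_case Positive group-mean intensities (vectorized).
#' @return Signed fold change(s).
#' @examples
#' signed_fold_change(0.109, 0.198) # 1.82 to 2 decimals
#' @export
signed_fold_change <- function(nfi_control, nfi_case) {
  if (any(!is.finite(nfi_control)) || any(!is.finite(nfi_case)) ||
      any(nfi_control <= 0) || any(nfi_case <= 0)) {
    stop("undefined fold change: NFIs must be positive and finite")
  }
  r <- nfi_case / nfi_control
  ifelse(r >= 1, r, -1 / r)
}

#' Fold-change table from group NFIs
#'
#' @param group_nfi data.frame `group`, `lectin`, `nfi` from
#'   [aggregate_sample()].
#' @param control,case Group labels taken as control and case.
#' @return data.frame `lectin`, `nfi_control`, `nfi_case`, `fc`. Lectins
#'   missing in either group are dropped.
#' @export
lectin_fold_changes <- function(group_nfi, control = "control", case = "case") {
  a <- group_nfi[group_nfi$group == control, c("lectin", "nfi")]
  b <- group_nfi[group_nfi$group == case, c("lectin", "nfi")]
  names(a)[2] <- "nfi_control"
  names(b)[2] <- "nfi_case"
  fc <- merge(a, b, by = "lectin")
  fc <- fc[stats::complete.cases(fc), , drop = FALSE]
  fc$fc <- signed_fold_change(fc$nfi_control, fc$nfi_case)
  fc <- fc[order(fc$lectin), ]
  rownames(fc) <- NULL
  fc
}

#' Call significantly regulated lectins at a fold-change threshold
#'
#' A lectin is called `up` when `fc >= threshold`, `down` when
#' `fc <= -threshold` (both inclusive), otherwise `unchanged`.
#'
#' @param fc_table data.frame with columns `lectin` and `fc`.
#' @param threshold Fold-change threshold (default 1.2, must be >= 1).
#' @return Input with an added `call` column; attribute `n_significant`
#'   counts non-unchanged lectins.
#' @export
call_significant_lectins <- function(fc_table, threshold = 1.2) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 1) {
    stop("threshold must be a single number >= 1")
  }
  call <- ifelse(fc_table$fc >= threshold, "up",
                 ifelse(fc_table$fc <= -threshold, "down", "unchanged"))
  out <- fc_table
  out$call <- call
  attr(out, "n_significant") <- sum(call != "unchanged")
  out
}

#' Write a fold-change table as TSV
#'
#' @param fc_table data.frame with (at least) `lectin`, `nfi_control`,
#'   `nfi_case`, `fc`, `call`.
#' @param path Output path.
#' @export
write_fold_change_tsv <- function(fc_table, path) {
  utils::write.table(fc_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
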