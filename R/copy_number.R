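# arm-level copy-number classification: bin calls -> arm events -> CAE
# scoring -> molecular risk flags

#' Construct a binned copy-number profile
#'
#' A copy-number profile is an ordered table of non-overlapping genomic bins
#' (0-based half-open coordinates) carrying a per-bin \code{log2ratio}
#' relative to the diploid state and/or a categorical \code{call}
#' (\code{"loss"}, \code{"normal"}, \code{"gain"}). Bins are re-sorted by
#' chromosome and start on construction, so downstream results do not depend
#' on input row order.
#'
#' @param sample_id sample identifier.
#' @param bins data.frame with columns \code{chrom}, \code{start},
#'   \code{end} and at least one of \code{log2ratio}, \code{call}.
#' @param build genome build tag (informational), default \code{"hg38"}.
#' @return an object of class \code{cn_profile} (a data.frame of bins with
#'   attributes \code{sample_id} and \code{build}).
#' @export
cn_profile <- function(sample_id, bins, build = "hg38") {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(bins))) {
    stop("bins need columns chrom, start, end", call. = FALSE)
  }
  if (!("log2ratio" %in% names(bins)) && !("call" %in% names(bins))) {
    stop("bins need a log2ratio and/or a call column", call. = FALSE)
  }
  bins <- as.data.frame(bins)
  ord <- order(.chrom_rank(bins$chrom), bins$start)
  bins <- bins[ord, , drop = FALSE]
  rownames(bins) <- NULL
  if (any(bins$end <= bins$start)) {
    stop("bins must satisfy end > start", call. = FALSE)
  }
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)])) {
      stop("overlapping bins on ", ch, call. = FALSE)
    }
  }
  if ("call" %in% names(bins) &&
      !all(bins$call %in% c("loss", "normal", "gain"))) {
    stop("calls must be 'loss', 'normal' or 'gain'", call. = FALSE)
  }
  structure(bins, sample_id = sample_id, build = build,
            class = c("cn_profile", "data.frame"))
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("<cn_profile> sample %s (%s): %d bins on %d chromosome(s)\n",
              attr(x, "sample_id"), attr(x, "build"), nrow(x),
              length(unique(x$chrom))))
  if ("call" %in% names(x)) {
    print(table(call = x$call))
  }
  invisible(x)
}

#' Threshold per-bin log2 ratios into categorical calls
#'
#' Deterministic three-state caller: a bin is a \code{gain} when its
#' log2ratio is at or above \code{gain_threshold}, a \code{loss} when at or
#' below \code{loss_threshold}, and \code{normal} in the open band between.
#' Re-calling an already called profile with the same thresholds is a no-op;
#' a profile carrying calls but no log2 ratios is returned unchanged.
#'
#' @param profile a \code{\link{cn_profile}}.
#' @param gain_threshold positive log2-ratio cutoff, default \code{0.1}.
#' @param loss_threshold negative log2-ratio cutoff, default \code{-0.1}.
#' @return the profile with a \code{call} column.
#' @examples
#' p <- cn_profile("s1", data.frame(chrom = "chr8", start = 0, end = 1e5,
#'                                  log2ratio = 0.3))
#' call_bins(p)$call
#' @export
call_bins <- function(profile, gain_threshold = 0.1, loss_threshold = -0.1) {
  stopifnot(inherits(profile, "cn_profile"))
  if (!(loss_threshold < 0 && 0 < gain_threshold)) {
    stop("need loss_threshold < 0 < gain_threshold", call. = FALSE)
  }
  if (!("log2ratio" %in% names(profile))) {
    if ("call" %in% names(profile)) return(profile)
    stop("profile has neither log2ratio nor call", call. = FALSE)
  }
  if (anyNA(profile$log2ratio)) {
    stop("missing log2ratio values in profile ", attr(profile, "sample_id"),
         call. = FALSE)
  }
  lr <- profile$log2ratio
  profile$call <- ifelse(lr >= gain_threshold, "gain",
                         ifelse(lr <= loss_threshold, "loss", "normal"))
  profile
}

#' Construct an arm-event set
#'
#' @param sample_id sample identifier.
#' @param status named character vector mapping arm names (e.g. \code{"8q"})
#'   to \code{"gain"}, \code{"loss"} or \code{"neutral"}.
#' @return an object of class \code{arm_events} with the status map, the
#'   gain/loss/total alteration counts and the CAE count.
#' @export
arm_events <- function(sample_id, status) {
  stopifnot(is.character(status), !is.null(names(status)))
  if (!all(status %in% c("gain", "loss", "neutral"))) {
    stop("arm status must be gain/loss/neutral", call. = FALSE)
  }
  n_gains <- sum(status == "gain")
  n_losses <- sum(status == "loss")
  structure(list(sample_id = sample_id, status = status,
                 n_gains = n_gains, n_losses = n_losses,
                 n_cna = n_gains + n_losses, cae_count = count_cae(status)),
            class = "arm_events")
}

#' @export
print.arm_events <- function(x, ...) {
  altered <- x$status[x$status != "neutral"]
  cat(sprintf("<arm_events> %s: %d gains, %d losses (%d CNAs), %d CAEs\n",
              x$sample_id, x$n_gains, x$n_losses, x$n_cna, x$cae_count))
  if (length(altered)) {
    cat("  ", paste(names(altered), altered, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Derive arm-level events from a called profile
#'
#' Aggregates per-bin calls to arm status. An arm is called \code{gain}
#' (resp. \code{loss}) when at least \code{min_fraction} of its covered bins
#' are called gain (resp. loss); when both directions clear the fraction
#' threshold the direction with the larger fraction wins and an exact tie is
#' \code{neutral}. Arms with no covered bins are \code{neutral}. Bins are
#' assigned to the arm containing their midpoint; bins falling in no arm
#' (e.g. centromeric) are ignored.
#'
#' @param profile a called \code{\link{cn_profile}} (see
#'   \code{\link{call_bins}}).
#' @param arm_map arm definitions from \code{\link{read_arm_map}}.
#' @param min_fraction minimum fraction of covered bins altered in one
#'   direction, in [0.5, 1]; default \code{0.5}.
#' @return an \code{\link{arm_events}} object covering every arm of
#'   \code{arm_map}.
#' @export
derive_arm_events <- function(profile, arm_map, min_fraction = 0.5) {
  stopifnot(inherits(profile, "cn_profile"))
  if (nrow(profile) == 0L) stop("empty profile", call. = FALSE)
  if (!("call" %in% names(profile))) {
    stop("profile has no calls; run call_bins() first", call. = FALSE)
  }
  if (!(min_fraction >= 0.5 && min_fraction <= 1)) {
    stop("min_fraction must lie in [0.5, 1]", call. = FALSE)
  }
  .validate_arm_map(arm_map)
  missing_chrom <- setdiff(unique(profile$chrom), unique(arm_map$chrom))
  if (length(missing_chrom)) {
    stop("arm map does not cover chromosome(s): ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  mid <- (profile$start + profile$end) / 2
  arm_of <- rep(NA_character_, nrow(profile))
  for (i in seq_len(nrow(arm_map))) {
    hit <- profile$chrom == arm_map$chrom[i] &
      mid >= arm_map$start[i] & mid < arm_map$end[i]
    arm_of[hit] <- arm_map$arm[i]
  }
  status <- stats::setNames(rep("neutral", nrow(arm_map)), arm_map$arm)
  covered <- !is.na(arm_of)
  if (any(covered)) {
    for (a in unique(arm_of[covered])) {
      calls <- profile$call[covered & arm_of == a]
      f_gain <- mean(calls == "gain")
      f_loss <- mean(calls == "loss")
      if (f_gain >= min_fraction && f_gain > f_loss) {
        status[a] <- "gain"
      } else if (f_loss >= min_fraction && f_loss > f_gain) {
        status[a] <- "loss"
      }
    }
  }
  arm_events(attr(profile, "sample_id"), status)
}

#' Count cancer-associated events
#'
#' Counts how many of the seven direction-specific CAEs are present: gains
#' of 8q, 13q, 20q and losses of 8p, 15q, 17p, 18q. An alteration of a CAE
#' arm in the wrong direction does not count.
#'
#' @param events an \code{\link{arm_events}} object or a named status
#'   vector.
#' @return integer in 0..7.
#' @examples
#' count_cae(c("8q" = "gain", "13q" = "gain", "17p" = "loss"))
#' @export
count_cae <- function(events) {
  status <- if (inherits(events, "arm_events")) events$status else events
  stopifnot(is.character(status), !is.null(names(status)))
  g <- sum(names(status) %in% CAE_GAIN_ARMS & status == "gain")
  l <- sum(names(status) %in% CAE_LOSS_ARMS & status == "loss")
  as.integer(g + l)
}

#' Classify an adenoma's molecular risk
#'
#' Applies the four binary high-risk definitions: \code{high_cae} (>= 2
#' CAEs, the primary molecular high-risk definition), \code{high_cna} (>= 3
#' alterations of any direction), \code{high_gain} (>= 3 gains) and
#' \code{high_loss} (>= 3 losses). Burden is counted at arm resolution; a
#' whole-chromosome change therefore contributes two events (p and q).
#'
#' @param events an \code{\link{arm_events}} object.
#' @param cae_threshold CAE count defining molecular high risk, default 2.
#' @param burden_threshold alteration count defining the burden-based
#'   high-risk flags, default 3.
#' @return an object of class \code{molecular_risk}: the four logical flags
#'   plus the underlying counts.
#' @export
classify_molecular <- function(events, cae_threshold = 2,
                               burden_threshold = 3) {
  stopifnot(inherits(events, "arm_events"))
  structure(list(
    sample_id = events$sample_id,
    high_cae  = events$cae_count >= cae_threshold,
    high_cna  = events$n_cna >= burden_threshold,
    high_gain = events$n_gains >= burden_threshold,
    high_loss = events$n_losses >= burden_threshold,
    cae_count = events$cae_count,
    n_cna = events$n_cna, n_gains = events$n_gains,
    n_losses = events$n_losses
  ), class = "molecular_risk")
}

#' @export
print.molecular_risk <- function(x, ...) {
  cat(sprintf(paste0("<molecular_risk> %s: CAE=%d (high_cae=%s), CNA=%d, ",
                     "gains=%d, losses=%d\n"),
              x$sample_id, x$cae_count, x$high_cae, x$n_cna,
              x$n_gains, x$n_losses))
  invisible(x)
}

#' Cross-tabulate morphologic against molecular classification
#'
#' Builds the 2x2 table of molecular risk (high/low) by adenoma morphology
#' (advanced / non-advanced), with counts, within-column percentages
#' (fraction of each morphology class that is molecular high risk),
#' within-row percentages, and overall prevalences. Percentages are reported
#' to one decimal, rounding half away from zero.
#'
#' @param data data.frame with a \code{morphology} column
#'   (\code{"advanced"}/\code{"non_advanced"}) and the logical flag column
#'   named by \code{flag}.
#' @param flag name of the logical high-risk column, default
#'   \code{"high_cae"}.
#' @return an object of class \code{risk_crosstab}: count matrix
#'   (High/Low x advanced/non_advanced), column percentages, row
#'   percentages, and overall percentages.
#' @export
crosstab_morphology_molecular <- function(data, flag = "high_cae") {
  if (!all(c("morphology", flag) %in% names(data))) {
    stop("data needs columns 'morphology' and '", flag, "'", call. = FALSE)
  }
  morph <- data$morphology
  if (anyNA(morph) || !all(morph %in% c("advanced", "non_advanced"))) {
    stop("morphology must be 'advanced' or 'non_advanced' for every subject",
         call. = FALSE)
  }
  high <- data[[flag]]
  if (anyNA(high) || !is.logical(high)) {
    stop("flag column '", flag, "' must be logical and complete",
         call. = FALSE)
  }
  counts <- matrix(c(sum(high & morph == "advanced"),
                     sum(!high & morph == "advanced"),
                     sum(high & morph == "non_advanced"),
                     sum(!high & morph == "non_advanced")),
                   nrow = 2, dimnames = list(c("High", "Low"),
                                             c("advanced", "non_advanced")))
  n <- sum(counts)
  col_tot <- colSums(counts)
  row_tot <- rowSums(counts)
  structure(list(
    flag = flag,
    counts = counts,
    n = n,
    col_pct = sweep(counts, 2, col_tot, function(x, t) pct(x / t)),
    row_pct = sweep(counts, 1, row_tot, function(x, t) pct(x / t)),
    overall_pct = stats::setNames(pct(row_tot / n), rownames(counts)),
    morph_pct = stats::setNames(pct(col_tot / n), colnames(counts))
  ), class = "risk_crosstab")
}

#' @export
print.risk_crosstab <- function(x, ...) {
  cat(sprintf("Molecular (%s) x morphologic classification, n = %d\n",
              x$flag, x$n))
  disp <- matrix(sprintf("%d (%.1f)", x$counts, x$col_pct),
                 nrow = 2, dimnames = dimnames(x$counts))
  disp <- cbind(disp, Total = sprintf("%d (%.1f)", rowSums(x$counts),
                                      x$overall_pct))
  print(disp, quote = FALSE)
  invisible(x)
}

#' @rdname crosstab_morphology_molecular
#' @param x a \code{risk_crosstab}.
#' @param ... unused.
#' @export
as.data.frame.risk_crosstab <- function(x, ...) {
  data.frame(molecular = rep(rownames(x$counts), 2),
             morphology = rep(colnames(x$counts), each = 2),
             n = as.vector(x$counts),
             pct_within_morphology = as.vector(x$col_pct),
             pct_within_molecular = as.vector(x$row_pct))
}
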