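# plain-text readers and writers: cohort tables, bin tables, SEG files

#' Write / read a cohort table
#'
#' Tab-delimited text with a header row; one row per subject. The
#' \code{true_arm_events} list column is not serialised (the derived counts
#' and flags are), so a round-tripped cohort supports matching and
#' regression but not profile regeneration.
#'
#' @param cohort a cohort data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort[, setdiff(names(cohort), "true_arm_events"), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  class(df) <- c("cohort", "data.frame")
  df
}

#' Write / read a bin-level copy-number table
#'
#' Tab-delimited \code{chrom}, \code{start}, \code{end}, \code{log2ratio}
#' and optionally \code{call}; 0-based half-open coordinates.
#'
#' @param profile a \code{\link{cn_profile}}.
#' @param path file path.
#' @return the path (write) or a \code{cn_profile} (read), invisibly for
#'   write.
#' @export
write_bin_table <- function(profile, path) {
  stopifnot(inherits(profile, "cn_profile"))
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_table
#' @param sample_id sample id to attach on read; default the file stem.
#' @param build genome build tag.
#' @export
read_bin_table <- function(path, sample_id = NULL, build = "hg38") {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  cn_profile(sample_id, df, build = build)
}

#' Write profiles as a SEG file
#'
#' Collapses each called profile into maximal runs of bins with a common
#' call per chromosome and writes the standard SEG columns (ID, chrom,
#' loc.start, loc.end, num.mark, seg.mean), 0-based half-open.
#'
#' @param profiles a list of called \code{\link{cn_profile}} objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_seg <- function(profiles, path) {
  rows <- list()
  for (pr in profiles) {
    stopifnot(inherits(pr, "cn_profile"))
    if (!("call" %in% names(pr))) {
      stop("profiles must be called before SEG export", call. = FALSE)
    }
    for (ch in unique(pr$chrom)) {
      b <- pr[pr$chrom == ch, , drop = FALSE]
      # break runs at call changes and at coverage gaps
      brk <- c(TRUE, b$call[-1L] != b$call[-nrow(b)] |
                 b$start[-1L] != b$end[-nrow(b)])
      run <- cumsum(brk)
      for (r in unique(run)) {
        seg <- b[run == r, , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          ID = attr(pr, "sample_id"), chrom = ch,
          loc.start = min(seg$start), loc.end = max(seg$end),
          num.mark = nrow(seg),
          seg.mean = mean(seg$log2ratio)
        )
      }
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a SEG file into copy-number profiles
#'
#' Each segment becomes one (variable-width) bin carrying the segment mean.
#' Note that arm-event derivation counts bins, so SEG input should be
#' re-binned to comparable widths when segment lengths are very uneven.
#'
#' @param path SEG file path (columns ID, chrom, loc.start, loc.end,
#'   num.mark, seg.mean).
#' @param build genome build tag.
#' @return named list of \code{\link{cn_profile}} objects.
#' @export
read_seg <- function(path, build = "hg38") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("ID", "chrom", "loc.start", "loc.end", "seg.mean")
  if (!all(need %in% names(df))) {
    stop("SEG file lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  lapply(split(df, df$ID), function(d) {
    cn_profile(as.character(d$ID[1]),
               data.frame(chrom = d$chrom, start = d$loc.start,
                          end = d$loc.end, log2ratio = d$seg.mean),
               build = build)
  })
}

# write a data.frame as TSV (the pipeline's table writer)
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# write a list as pretty JSON with bare scalars
.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
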