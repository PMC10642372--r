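# chromosome-arm definitions from cytoBand-format files

# short arms of the acrocentric chromosomes carry only rDNA/satellite
# sequence and are not callable from binned coverage data
.ACROCENTRIC_P <- c("13p", "14p", "15p", "21p", "22p")

# the seven direction-specific cancer-associated events (CAEs): recurrent
# arm-level changes of the colorectal adenoma-to-carcinoma transition
CAE_GAIN_ARMS <- c("8q", "13q", "20q")
CAE_LOSS_ARMS <- c("8p", "15q", "17p", "18q")

#' Read chromosome-arm definitions from a cytoBand file
#'
#' Parses a UCSC cytoBand-dialect file (tab-delimited: chrom, start, end,
#' band name, Giemsa stain; 0-based half-open coordinates) and collapses the
#' bands of each chromosome into p- and q-arm intervals. Centromeric
#' (\code{acen}) bands are excluded, so each arm spans its euchromatic
#' bands only. The package ships an arm-resolution hg38 file for the
#' autosomes (one band per arm plus the centromere), which is the default.
#'
#' @param path path to a cytoBand-format file; default is the packaged hg38
#'   arm map.
#' @param exclude_acrocentric drop the uncallable short arms of the
#'   acrocentric chromosomes (13p, 14p, 15p, 21p, 22p)? Default \code{TRUE}.
#' @return a data.frame with columns \code{chrom}, \code{arm} (e.g.
#'   \code{"8q"}), \code{start}, \code{end}, one row per arm, sorted by
#'   chromosome and arm. Attribute \code{"genome"} carries the build tag.
#' @examples
#' arms <- read_arm_map()
#' subset(arms, arm %in% c("8p", "8q"))
#' @export
read_arm_map <- function(path = NULL, exclude_acrocentric = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "cytoBand_hg38_arms.txt",
                        package = "adenomaRisk", mustWork = TRUE)
  }
  bands <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "start", "end",
                                           "name", "stain"),
                             colClasses = c("character", "numeric", "numeric",
                                            "character", "character"))
  if (nrow(bands) == 0L) stop("empty cytoBand file: ", path, call. = FALSE)
  bands <- bands[bands$stain != "acen", , drop = FALSE]
  arm_letter <- substr(bands$name, 1L, 1L)
  if (!all(arm_letter %in% c("p", "q"))) {
    stop("cytoBand band names must start with 'p' or 'q'", call. = FALSE)
  }
  chrom_plain <- sub("^chr", "", bands$chrom)
  key <- paste0(chrom_plain, arm_letter)
  arms <- data.frame(
    chrom = tapply(bands$chrom, key, `[`, 1L)[unique(key)],
    arm   = unique(key),
    start = as.numeric(tapply(bands$start, key, min)[unique(key)]),
    end   = as.numeric(tapply(bands$end, key, max)[unique(key)]),
    row.names = NULL
  )
  if (exclude_acrocentric) {
    arms <- arms[!(arms$arm %in% .ACROCENTRIC_P), , drop = FALSE]
  }
  ord <- order(.chrom_rank(arms$chrom), arms$start)
  arms <- arms[ord, , drop = FALSE]
  rownames(arms) <- NULL
  .validate_arm_map(arms)
  attr(arms, "genome") <- "user"
  if (grepl("hg38", basename(path))) attr(arms, "genome") <- "hg38"
  arms
}

.validate_arm_map <- function(arms) {
  stopifnot(all(c("chrom", "arm", "start", "end") %in% names(arms)))
  if (anyDuplicated(arms$arm)) {
    stop("overlapping/duplicated arm definitions in arm map", call. = FALSE)
  }
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (any(a$end <= a$start)) {
      stop("arm map has empty interval on ", ch, call. = FALSE)
    }
    if (nrow(a) > 1L && any(a$start[-1L] < a$end[-nrow(a)])) {
      stop("overlapping arm definitions on ", ch, call. = FALSE)
    }
  }
  invisible(arms)
}

# numeric ordering of chromosome names ("chr2" before "chr10")
.chrom_rank <- function(chrom) {
  plain <- sub("^chr", "", chrom)
  rank <- suppressWarnings(as.numeric(plain))
  rank[plain == "X"] <- 23
  rank[plain == "Y"] <- 24
  if (anyNA(rank)) stop("unrecognised chromosome name(s): ",
                        paste(unique(chrom[is.na(rank)]), collapse = ", "),
                        call. = FALSE)
  rank
}

#' The seven cancer-associated events
#'
#' Returns the direction-specific arm alterations counted as
#' cancer-associated events (CAEs): gains of 8q, 13q and 20q, and losses of
#' 8p, 15q, 17p and 18q.
#'
#' @return data.frame with columns \code{arm} and \code{direction}.
#' @export
cae_definition <- function() {
  data.frame(arm = c(CAE_GAIN_ARMS, CAE_LOSS_ARMS),
             direction = rep(c("gain", "loss"),
                             c(length(CAE_GAIN_ARMS), length(CAE_LOSS_ARMS))))
}
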