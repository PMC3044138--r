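#' Construct a per-site signal set
#'
#' The basic container for raw or normalized two-channel array intensities.
#' For the `"infinium"` platform the two channels are the unmethylated (A)
#' and methylated (B) probe intensities per sample; for `"msre"` they are
#' the undigested (HpaII-) and HpaII-digested (HpaII+) signals per pool.
#'
#' @param platform `"infinium"` or `"msre"`.
#' @param sites data.frame with columns `site_id`, `chrom`, `pos`
#'   (0-based positions).
#' @param ch1,ch2 numeric matrices, sites x samples, finite and >= 0.
#'   `ch1` is A (infinium) or HpaII- (msre); `ch2` is B or HpaII+.
#'   Column names are sample ids beginning with the group label
#'   (`CVS` or `MBC`).
#' @param groups optional factor/character of per-sample groups; inferred
#'   from column-name prefixes when omitted.
#' @return An object of class `signal_set`: a list with elements
#'   `platform`, `sites`, `ch1`, `ch2`, `groups`, `channel_names`.
#' @export
signal_set <- function(platform, sites, ch1, ch2, groups = NULL) {
  platform <- match.arg(platform, c("infinium", "msre"))
  stopifnot(is.data.frame(sites),
            all(c("site_id", "chrom", "pos") %in% names(sites)))
  ch1 <- as.matrix(ch1)
  ch2 <- as.matrix(ch2)
  if (nrow(ch1) != nrow(sites) || nrow(ch2) != nrow(sites) ||
      ncol(ch1) != ncol(ch2)) {
    stop("channel matrices must be sites x samples and congruent",
         call. = FALSE)
  }
  if (anyNA(ch1) || anyNA(ch2) ||
      any(!is.finite(ch1)) || any(!is.finite(ch2))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (any(ch1 < 0) || any(ch2 < 0)) {
    stop("negative intensity encountered; intensities must be >= 0",
         call. = FALSE)
  }
  if (anyDuplicated(sites$site_id)) {
    stop("duplicate site_id values are not allowed", call. = FALSE)
  }
  if (any(sites$pos < 0)) stop("positions must be >= 0", call. = FALSE)
  samples <- colnames(ch1)
  if (is.null(samples)) {
    stop("channel matrices must carry sample ids as column names",
         call. = FALSE)
  }
  if (!identical(samples, colnames(ch2))) {
    stop("both channels must cover the same samples in the same order",
         call. = FALSE)
  }
  if (is.null(groups)) groups <- infer_groups(samples)
  groups <- factor(as.character(groups), levels = c("CVS", "MBC"))
  if (anyNA(groups) || length(groups) != length(samples)) {
    stop("sample groups must be CVS or MBC, one per sample", call. = FALSE)
  }

  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    warning("input sites were not sorted by (chrom, pos); sorting",
            call. = FALSE)
    sites <- sites[ord, , drop = FALSE]
    ch1 <- ch1[ord, , drop = FALSE]
    ch2 <- ch2[ord, , drop = FALSE]
  }
  dup <- unlist(lapply(split(sites$pos, sites$chrom),
                       function(p) any(duplicated(p))))
  if (any(dup)) {
    stop("site positions must be strictly increasing within a chromosome",
         call. = FALSE)
  }
  rownames(sites) <- NULL
  rownames(ch1) <- rownames(ch2) <- sites$site_id
  channel_names <- if (platform == "infinium") c("A", "B") else c("U", "D")
  structure(list(platform = platform, sites = sites, ch1 = ch1, ch2 = ch2,
                 groups = groups, channel_names = channel_names),
            class = "signal_set")
}

infer_groups <- function(samples) {
  g <- rep(NA_character_, length(samples))
  g[startsWith(samples, "CVS")] <- "CVS"
  g[startsWith(samples, "MBC")] <- "MBC"
  g
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("signal_set [%s]: %d sites x %d samples (%s)\n",
              x$platform, nrow(x$sites), ncol(x$ch1),
              paste(sprintf("%s=%d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  cat("channels:", paste(x$channel_names, collapse = "/"),
      " chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / sites in a signal set
#' @param x a `signal_set`.
#' @return `dim.signal_set` returns `c(n_sites, n_samples)`.
#' @export
dim.signal_set <- function(x) c(nrow(x$sites), ncol(x$ch1))
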