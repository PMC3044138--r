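#' Read a per-site signal table
#'
#' Reads the tab-separated signal format used throughout the pipeline:
#' columns `site_id`, `chrom`, `pos` (0-based), then two intensity columns
#' per sample named `<channel>.<sample>` where the channel prefix is
#' `A`/`B` for the infinium platform and `U`/`D` (undigested HpaII- /
#' digested HpaII+) for the msre platform.  Sample ids must begin with
#' their group label, `CVS` or `MBC`.
#'
#' @param path path to a TSV file with a header row.
#' @param platform `"infinium"` or `"msre"`.
#' @return A validated [signal_set()] sorted by (chrom, pos).
#' @export
read_signal_table <- function(path, platform) {
  platform <- match.arg(platform, c("infinium", "msre"))
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("site_id", "chrom", "pos")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("signal table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  prefixes <- if (platform == "infinium") c("A", "B") else c("U", "D")
  ch_cols <- lapply(prefixes, function(p) {
    grep(paste0("^", p, "\\."), names(df), value = TRUE)
  })
  s1 <- sub("^[AUBD]\\.", "", ch_cols[[1]])
  s2 <- sub("^[AUBD]\\.", "", ch_cols[[2]])
  if (!length(s1) || !setequal(s1, s2)) {
    stop("signal table must have matched '", prefixes[1], ".<sample>' and '",
         prefixes[2], ".<sample>' columns for every sample", call. = FALSE)
  }
  samples <- s1
  ch1 <- as.matrix(df[, paste0(prefixes[1], ".", samples), drop = FALSE])
  ch2 <- as.matrix(df[, paste0(prefixes[2], ".", samples), drop = FALSE])
  colnames(ch1) <- colnames(ch2) <- samples
  sites <- df[, need]
  sites$pos <- as.integer(sites$pos)
  signal_set(platform, sites, ch1, ch2)
}

#' Write a per-site signal table
#'
#' Inverse of [read_signal_table()]; writing then re-reading is the
#' identity on all fields.
#'
#' @param x a `signal_set`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_signal_table <- function(x, path) {
  stopifnot(inherits(x, "signal_set"))
  prefixes <- if (x$platform == "infinium") c("A", "B") else c("U", "D")
  samples <- colnames(x$ch1)
  out <- x$sites
  c1 <- as.data.frame(x$ch1)
  names(c1) <- paste0(prefixes[1], ".", samples)
  c2 <- as.data.frame(x$ch2)
  names(c2) <- paste0(prefixes[2], ".", samples)
  out <- cbind(out, c1, c2)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a region set as BED6
#'
#' Regions are written 0-based half-open with `name` = region type and
#' `score` = round(-10 log10(min adjusted p)) capped at 1000, preceded by a
#' single `track` header line.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`, `type`,
#'   and (optionally) `min_p_adj`.
#' @param path output path.
#' @param track_name name written in the track header.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path, track_name = "tdmrscan_regions") {
  stopifnot(is.data.frame(regions))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track name=\"%s\"", track_name), con)
  if (!nrow(regions)) {
    return(invisible(path))
  }
  stopifnot(all(c("chrom", "start", "end", "type") %in% names(regions)))
  if (any(regions$start >= regions$end)) {
    stop("regions must satisfy start < end (0-based half-open)",
         call. = FALSE)
  }
  p <- if ("min_p_adj" %in% names(regions)) regions$min_p_adj else rep(1, nrow(regions))
  score <- pmin(1000, round(-10 * log10(pmax(p, 1e-300))))
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    name = regions$type,
                    score = score,
                    strand = ".")
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file written by [write_regions_bed()]
#'
#' @param path BED path (track header lines are skipped).
#' @return data.frame with `chrom`, `start`, `end`, `type`, `score`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), type = character(),
                      score = numeric()))
  }
  df <- read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:5] <- c("chrom", "start", "end", "type", "score")
  df[, 1:5]
}

#' Read / write genome annotation tables
#'
#' The annotation interchange format is three TSV tables sharing a
#' 0-based half-open interval convention: `genes` (gene_id, chrom, start,
#' end, strand, tss), `exons` (gene_id, chrom, start, end) and `cgis`
#' (chrom, start, end).
#'
#' @param annotation a list with data.frames `genes`, `exons`, `cgis`.
#' @param dir directory holding `genes.tsv`, `exons.tsv`, `cgis.tsv`.
#' @return `read_annotation` returns the annotation list;
#'   `write_annotation` returns `dir` invisibly.
#' @export
write_annotation <- function(annotation, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("genes", "exons", "cgis")) {
    write.table(annotation[[nm]], file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(dir) {
  ann <- lapply(c(genes = "genes", exons = "exons", cgis = "cgis"),
                function(nm) {
                  read.delim(file.path(dir, paste0(nm, ".tsv")),
                             stringsAsFactors = FALSE)
                })
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  stopifnot(all(c("genes", "exons", "cgis") %in% names(ann)))
  g <- ann$genes
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand", "tss")
                %in% names(g)))
  if (any(g$start >= g$end)) {
    stop("gene intervals must satisfy start < end", call. = FALSE)
  }
  plus <- g$strand == "+"
  if (any(g$tss[plus] != g$start[plus]) ||
      any(g$tss[!plus] != g$end[!plus] - 1L)) {
    stop("tss must equal start on + strand and end - 1 on - strand",
         call. = FALSE)
  }
  e <- ann$exons
  if (nrow(e)) {
    idx <- match(e$gene_id, g$gene_id)
    if (anyNA(idx) || any(e$start < g$start[idx]) || any(e$end > g$end[idx])) {
      stop("exons must lie within their gene body", call. = FALSE)
    }
  }
  invisible(ann)
}
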