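#' Promoter window around a TSS
#'
#' Platform-specific promoter definition: 1500 bp upstream to 1500 bp
#' downstream of the TSS for the infinium analysis, 1500 bp upstream to
#' 1000 bp downstream for the msre analysis.  On the minus strand the
#' window is mirrored about the TSS.  Intervals are 0-based half-open and
#' clipped at 0.
#'
#' @param tss TSS position(s), 0-based.
#' @param strand `"+"` or `"-"` (vectorized).
#' @param platform `"infinium"` or `"msre"`.
#' @param upstream,downstream window sizes in bp; defaults per platform.
#' @return data.frame with `start` and `end`.
#' @export
promoter_window <- function(tss, strand, platform,
                            upstream = 1500L,
                            downstream = NULL) {
  platform <- match.arg(platform, c("infinium", "msre"))
  if (is.null(downstream)) {
    downstream <- if (platform == "infinium") 1500L else 1000L
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  plus <- strand == "+"
  start <- ifelse(plus, tss - upstream, tss - downstream + 1L)
  end <- ifelse(plus, tss + downstream, tss + upstream + 1L)
  data.frame(start = pmax(0L, as.integer(start)), end = as.integer(end))
}

sites_in_intervals <- function(chrom, pos, ichrom, istart, iend) {
  if (!length(ichrom)) return(logical(length(pos)))
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start = pos + 1L, width = 1L))
  s <- GenomicRanges::GRanges(ichrom,
                              IRanges::IRanges(start = istart + 1L,
                                               end = iend))
  IRanges::overlapsAny(q, s)
}

#' Annotate sites with genomic-feature membership
#'
#' Flags each site as lying inside a gene body (`[gene start, gene end)`),
#' a platform-specific promoter window, an exon, or a CpG island, by
#' half-open interval containment of the 0-based site position (start
#' inclusive, end exclusive).  Chromosomes absent from the annotation give
#' all-false flags.
#'
#' @param sites data.frame with `site_id`, `chrom`, `pos` (or a
#'   `signal_set`, whose site table is used).
#' @param annotation annotation list with `genes`, `exons`, `cgis` (see
#'   [read_annotation()]).
#' @param platform promoter convention, `"infinium"` or `"msre"`.
#' @return data.frame with `site_id` and logical `in_gene_body`,
#'   `in_promoter`, `in_exon`, `in_cgi`.
#' @export
annotate_sites <- function(sites, annotation, platform) {
  if (inherits(sites, "signal_set")) sites <- sites$sites
  validate_annotation(annotation)
  g <- annotation$genes
  prom <- promoter_window(g$tss, g$strand, platform)
  data.frame(
    site_id = sites$site_id,
    in_gene_body = sites_in_intervals(sites$chrom, sites$pos,
                                      g$chrom, g$start, g$end),
    in_promoter = sites_in_intervals(sites$chrom, sites$pos,
                                     g$chrom, prom$start, prom$end),
    in_exon = sites_in_intervals(sites$chrom, sites$pos,
                                 annotation$exons$chrom,
                                 annotation$exons$start,
                                 annotation$exons$end),
    in_cgi = sites_in_intervals(sites$chrom, sites$pos,
                                annotation$cgis$chrom,
                                annotation$cgis$start,
                                annotation$cgis$end),
    stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test with the point-probability two-sided
#' criterion: the p value is the sum of probabilities of all tables with
#' the observed margins whose point probability does not exceed that of
#' the observed table (within relative tolerance 1e-7).  The odds ratio is
#' the sample cross-product `ad/bc` (`Inf` or 0 at zero cells, `NaN` for
#' 0/0).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio`, `p`, and the input `table`.
#' @export
fisher_exact_two_sided <- function(table) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b          # row 1 total
  n1 <- a + c_         # column 1 total
  tot <- a + b + c_ + d
  if (tot == 0) stop("at least one margin must be non-zero", call. = FALSE)
  lo <- max(0, n1 - (tot - m1))
  hi <- min(m1, n1)
  support <- lo:hi
  dens <- dhyper(support, m1, tot - m1, n1)
  d_obs <- dens[match(a, support)]
  p <- min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c_)
  list(odds_ratio = or, p = p, table = tab)
}

#' Feature enrichment of one site status against another
#'
#' Builds the 2x2 table (status_a vs status_b) x (inside vs outside a
#' feature) from a methylation call table and a feature-membership table,
#' and applies [fisher_exact_two_sided()].  Also reports the
#' inside-feature proportion per status class (bar-plot data).
#'
#' @param calls methylation call table with `site_id` and `status`.
#' @param membership output of [annotate_sites()].
#' @param status_a,status_b the two status classes to compare (rows).
#' @param feature one of `"in_gene_body"`, `"in_promoter"`, `"in_exon"`,
#'   `"in_cgi"`.
#' @return List with `table`, `odds_ratio`, `p`, and `proportions`
#'   (named inside-feature proportions for the two classes).
#' @export
enrichment_by_feature <- function(calls, membership, status_a, status_b,
                                  feature) {
  feature <- match.arg(feature, c("in_gene_body", "in_promoter",
                                  "in_exon", "in_cgi"))
  flags <- membership[[feature]][match(calls$site_id, membership$site_id)]
  if (anyNA(flags)) stop("membership missing for some sites", call. = FALSE)
  ina <- calls$status == status_a
  inb <- calls$status == status_b
  if (!any(ina)) stop("no sites with status '", status_a, "'", call. = FALSE)
  if (!any(inb)) stop("no sites with status '", status_b, "'", call. = FALSE)
  tab <- rbind(c(sum(ina & flags), sum(ina & !flags)),
               c(sum(inb & flags), sum(inb & !flags)))
  dimnames(tab) <- list(c(status_a, status_b), c("inside", "outside"))
  ft <- fisher_exact_two_sided(tab)
  props <- tab[, "inside"] / rowSums(tab)
  list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p,
       proportions = props)
}

#' GO-style term enrichment of a gene set
#'
#' Fisher test of whether a term is over-represented in a gene set
#' relative to *all other* annotated genes in the universe: the 2x2 table
#' has rows (in set / in universe but not in set) and columns (has term /
#' lacks term), so the complement row excludes the set itself.
#'
#' @param gene_set character vector of gene ids (must be a strict subset
#'   of `universe`).
#' @param universe character vector of annotated gene ids.
#' @param term_map named logical vector over `universe`: does the gene
#'   carry the term?
#' @return As [fisher_exact_two_sided()], with the constructed `table`.
#' @export
go_term_enrichment <- function(gene_set, universe, term_map) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe)) {
    stop("gene_set must be a subset of the universe", call. = FALSE)
  }
  rest <- setdiff(universe, gene_set)
  if (!length(rest)) {
    stop("gene_set equals the universe; the complement is empty",
         call. = FALSE)
  }
  has <- term_map[universe]
  if (anyNA(has)) stop("term_map must cover the whole universe",
                       call. = FALSE)
  in_set <- universe %in% gene_set
  tab <- rbind(c(sum(in_set & has), sum(in_set & !has)),
               c(sum(!in_set & has), sum(!in_set & !has)))
  dimnames(tab) <- list(c("in_set", "other"), c("term", "no_term"))
  fisher_exact_two_sided(tab)
}
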