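#' Default parameters of the annotation simulator
#'
#' @return Named list: `gene_length_meanlog`/`gene_length_sdlog`
#'   (lognormal gene lengths, clamped to `gene_length_range`), `max_exons`,
#'   `promoter_seq_length` (bp of promoter sequence emitted per gene),
#'   `oe_modes`/`oe_sd`/`oe_range` (the low/high CpG observed-expected
#'   mixture: normals at 0.25 and 0.65, sd 0.08, truncated to
#'   (0.05, 1.5]), `oe_tol` (rejection tolerance on realized O/E),
#'   `cgi_fraction_high` (fraction of high-O/E promoters that get a CpG
#'   island), `cgi_halfwidth` (bp each side of the TSS), `min_gap`
#'   (bp between placed genes).
#' @export
annotation_sim_config <- function() {
  list(gene_length_meanlog = log(20000), gene_length_sdlog = 0.6,
       gene_length_range = c(3000, 150000),
       max_exons = 12L,
       promoter_seq_length = 2000L,
       oe_modes = c(0.25, 0.65), oe_sd = 0.08, oe_range = c(0.05, 1.5),
       oe_tol = 0.05,
       cgi_fraction_high = 0.6, cgi_halfwidth = 500L,
       min_gap = 4000L)
}

# first-order Markov sequences hitting per-gene CpG O/E targets.
# bases coded 1=A, 2=C, 3=G, 4=T; P(G | C) = target * q with q = 1/4,
# all other transitions uniform.  Rejection loop regenerates sequences
# whose realized O/E misses the target by more than tol.
simulate_promoter_sequences <- function(targets, L, tol) {
  ng <- length(targets)
  seqs <- matrix(0L, ng, L)
  active <- seq_len(ng)
  oe <- rep(NA_real_, ng)
  for (round in 1:100) {
    na <- length(active)
    m <- matrix(0L, na, L)
    m[, 1] <- sample.int(4L, na, replace = TRUE)
    p_cg <- targets[active] / 4
    for (j in 2:L) {
      u <- runif(na)
      cur <- m[, j - 1]
      nxt <- 1L + as.integer(floor(u * 4))  # uniform default
      isC <- cur == 2L
      if (any(isC)) {
        uc <- u[isC]
        pc <- p_cg[isC]
        w <- pmin(pmax((uc - pc) / (1 - pc), 0), 1)  # uniform over A, C, T
        alt <- c(1L, 2L, 4L)[1L + pmin(2L, as.integer(floor(w * 3)))]
        nxt[isC] <- ifelse(uc < pc, 3L, alt)
      }
      m[, j] <- nxt
    }
    n_c <- rowSums(m == 2L)
    n_g <- rowSums(m == 3L)
    n_cg <- rowSums(m[, -L, drop = FALSE] == 2L &
                      m[, -1, drop = FALSE] == 3L)
    realized <- ifelse(n_c > 0 & n_g > 0, n_cg * L / (n_c * n_g), NA)
    ok <- is.finite(realized) & abs(realized - targets[active]) <= tol
    seqs[active[ok], ] <- m[ok, , drop = FALSE]
    oe[active[ok]] <- realized[ok]
    active <- active[!ok]
    if (!length(active)) break
  }
  if (length(active)) {
    stop("could not reach the CpG O/E target for ", length(active),
         " promoter(s) after 100 attempts", call. = FALSE)
  }
  chars <- c("A", "C", "G", "T")
  list(seqs = apply(seqs, 1, function(r) paste(chars[r], collapse = "")),
       oe = oe)
}

#' Simulate a genome annotation with promoter sequences
#'
#' Places non-overlapping genes on the given chromosomes (lognormal
#' lengths, random strand, 1-12 exons inside each gene body), assigns
#' each promoter a CpG observed/expected target drawn from a two-mode
#' mixture (normals at 0.25 and 0.65, the low- and high-CpG promoter
#' classes), generates promoter sequences from a dinucleotide model tuned
#' to the target (regenerating until the realized O/E is within
#' `oe_tol`), and places a CpG island at 60 percent of high-O/E
#' promoters.  With `msre_truth` supplied and `gene_desert_coupling`
#' TRUE, genes (hence promoters and CGIs) avoid the planted difference
#' regions, making those regions gene-poor -- the EST-desert pattern of
#' broadly differentially methylated chromosomal domains.
#'
#' @param n_genes total genes to place.
#' @param config parameters from [annotation_sim_config()].
#' @param seed RNG seed.
#' @param chrom_lengths named vector of chromosome lengths (bp); derived
#'   from `msre_truth` when omitted.
#' @param msre_truth optional truth list from [generate_msre_dataset()].
#' @param gene_desert_coupling keep genes out of planted regions
#'   (default TRUE when `msre_truth` is given).
#' @return List with `genes` (gene_id, chrom, start, end, strand, tss,
#'   cpg_oe, oe_target, has_cgi), `exons`, `cgis`, and
#'   `promoter_seqs` (named character vector).
#' @export
generate_annotation <- function(n_genes = 400L,
                                config = annotation_sim_config(),
                                seed = 1L,
                                chrom_lengths = NULL,
                                msre_truth = NULL,
                                gene_desert_coupling = !is.null(msre_truth)) {
  cfg <- utils::modifyList(annotation_sim_config(), config)
  set.seed(seed)
  if (is.null(chrom_lengths)) {
    if (!is.null(msre_truth)) {
      chrom_lengths <- vapply(split(msre_truth$sites$pos,
                                    msre_truth$sites$chrom),
                              function(p) max(p) + 10000, numeric(1))
    } else {
      chrom_lengths <- c(chr13 = 1e7, chr18 = 1e7, chr21 = 6e6)
    }
  }
  avoid <- NULL
  if (gene_desert_coupling && !is.null(msre_truth)) {
    avoid <- msre_truth$regions
  }
  # apportion genes to chromosomes by length
  n_per <- round(n_genes * chrom_lengths / sum(chrom_lengths))
  n_per[1] <- n_genes - sum(n_per[-1])
  genes <- list()
  gi <- 0L
  for (ci in seq_along(chrom_lengths)) {
    chrom <- names(chrom_lengths)[ci]
    placed <- matrix(numeric(0), 0, 2)
    av <- if (is.null(avoid)) NULL else avoid[avoid$chrom == chrom, ]
    need <- n_per[ci]
    guard <- 0L
    while (nrow(placed) < need) {
      guard <- guard + 1L
      if (guard > 50 * need) {
        stop("could not place ", need, " genes on ", chrom, call. = FALSE)
      }
      L <- exp(rnorm(1, cfg$gene_length_meanlog, cfg$gene_length_sdlog))
      L <- round(min(max(L, cfg$gene_length_range[1]),
                     cfg$gene_length_range[2]))
      st <- round(runif(1, 5000, chrom_lengths[ci] - L - 5000))
      en <- st + L
      if (nrow(placed) &&
          any(st - cfg$min_gap < placed[, 2] &
                en + cfg$min_gap > placed[, 1])) next
      if (!is.null(av) && nrow(av) &&
          any(st - 2000 < av$end & en + 2000 > av$start)) next
      placed <- rbind(placed, c(st, en))
    }
    placed <- placed[order(placed[, 1]), , drop = FALSE]
    for (ri in seq_len(nrow(placed))) {
      gi <- gi + 1L
      strand <- sample(c("+", "-"), 1)
      st <- placed[ri, 1]
      en <- placed[ri, 2]
      genes[[gi]] <- data.frame(
        gene_id = sprintf("gene%04d", gi), chrom = chrom,
        start = st, end = en, strand = strand,
        tss = if (strand == "+") st else en - 1,
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$tss <- as.integer(genes$tss)
  ng <- nrow(genes)

  # exons: 1-12 ordered disjoint intervals inside the gene body
  exons <- lapply(seq_len(ng), function(i) {
    k <- sample.int(cfg$max_exons, 1)
    L <- genes$end[i] - genes$start[i]
    cuts <- sort(sample.int(L - 1, min(2 * k, L - 1)))
    if (length(cuts) %% 2) cuts <- cuts[-length(cuts)]
    if (!length(cuts)) return(NULL)
    st <- genes$start[i] + cuts[seq(1, length(cuts), 2)]
    en <- genes$start[i] + cuts[seq(2, length(cuts), 2)]
    data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
               start = as.integer(st), end = as.integer(en),
               stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, exons)
  rownames(exons) <- NULL

  # promoter CpG O/E targets: two-mode mixture, truncated
  mode <- sample(1:2, ng, replace = TRUE)
  targets <- rnorm(ng, cfg$oe_modes[mode], cfg$oe_sd)
  targets <- pmin(pmax(targets, cfg$oe_range[1] + 0.01), cfg$oe_range[2])
  ps <- simulate_promoter_sequences(targets, cfg$promoter_seq_length,
                                    cfg$oe_tol)
  genes$oe_target <- targets
  genes$cpg_oe <- ps$oe
  seqs <- setNames(ps$seqs, genes$gene_id)

  high <- which(genes$cpg_oe > 0.4)
  cgi_genes <- sample(high, round(cfg$cgi_fraction_high * length(high)))
  genes$has_cgi <- seq_len(ng) %in% cgi_genes
  cgis <- data.frame(chrom = genes$chrom[cgi_genes],
                     start = pmax(0L, genes$tss[cgi_genes] -
                                    cfg$cgi_halfwidth),
                     end = genes$tss[cgi_genes] + cfg$cgi_halfwidth,
                     stringsAsFactors = FALSE)
  cgis <- cgis[order(cgis$chrom, cgis$start), , drop = FALSE]
  rownames(cgis) <- NULL
  ann <- list(genes = genes, exons = exons, cgis = cgis,
              promoter_seqs = seqs)
  validate_annotation(ann)
  ann
}

#' Write promoter sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_promoter_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_promoter_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
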