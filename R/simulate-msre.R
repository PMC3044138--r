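#' Default parameters of the MSRE-array simulator
#'
#' Emulates a HpaII/MspI methylation-sensitive restriction-enzyme tiling
#' array over chromosomes 13, 18 and 21 (49,285 / 42,978 / 25,878 MspI
#' sites at full scale): exponential inter-site gaps, spatially clustered
#' background hypomethylation shared between tissues (two-state Markov
#' chain along site order), planted difference regions where one tissue
#' is hypomethylated and the other is not, and HpaII digestion that
#' removes signal in proportion to the unmethylated fraction.
#'
#' @return Named list of parameters:
#' \describe{
#'   \item{chrom_sites}{full-scale site counts per chromosome.}
#'   \item{scale}{scaling factor applied to the site counts (default 0.1,
#'     desk-scale).}
#'   \item{gap_mean}{mean inter-site distance in bp.}
#'   \item{hypo_rate}{stationary background hypomethylation rate.}
#'   \item{run_length}{mean length (sites) of background hypomethylated
#'     runs (Markov persistence).}
#'   \item{n_regions_fwd}{planted CVS-hypomethylated difference regions
#'     per chromosome.}
#'   \item{n_regions_rev}{total reversed (MBC-hypomethylated) regions
#'     across the genome, a 1:5 minority.}
#'   \item{region_sites}{range of planted region sizes in sites.}
#'   \item{d_unmeth, d_meth}{fraction of signal removed by digestion at
#'     unmethylated / methylated sites.}
#'   \item{total_mu, total_sigma, scale_range, noise_sd}{intensity model,
#'     as in [infinium_sim_config()].}
#' }
#' @export
msre_sim_config <- function() {
  list(chrom_sites = c(chr13 = 49285L, chr18 = 42978L, chr21 = 25878L),
       scale = 0.1,
       gap_mean = 2000,
       hypo_rate = 0.3,
       run_length = 30,
       n_regions_fwd = 8L,
       n_regions_rev = 5L,
       region_sites = c(60L, 200L),
       d_unmeth = 0.8, d_meth = 0.04,
       total_mu = 7, total_sigma = 0.4,
       scale_range = c(0.7, 1.4), noise_sd = 0.1)
}

# two-state Markov chain of hypomethylation flags with given stationary
# rate and mean hypo run length
markov_hypo_states <- function(n, rate, run_length) {
  a <- 1 / run_length                     # hypo -> meth
  b <- a * rate / (1 - rate)              # meth -> hypo
  s <- integer(n)
  s[1] <- rbinom(1, 1, rate)
  u <- runif(n)
  for (i in 2:n) {
    s[i] <- if (s[i - 1] == 1L) as.integer(u[i] >= a) else as.integer(u[i] < b)
  }
  s
}

# place non-overlapping index intervals of the given lengths in random
# order along the chromosome, keeping `margin` sites from the ends and
# between intervals; stick-breaking over the leftover space, so any
# feasible layout succeeds
place_index_regions <- function(n, lengths, margin) {
  m <- length(lengths)
  required <- sum(lengths) + margin * (m + 1)
  if (required > n) {
    stop("planted regions (", sum(lengths), " sites + margins) exceed the ",
         "chromosome size of ", n, " sites", call. = FALSE)
  }
  ord <- sample.int(m)                  # random genomic order
  free <- n - required
  cuts <- sort(c(0, sample.int(free + 1, m, replace = TRUE) - 1, free))
  gaps <- diff(cuts)[seq_len(m)]
  starts <- integer(m)
  cursor <- margin
  for (i in seq_len(m)) {
    cursor <- cursor + gaps[i]
    starts[ord[i]] <- cursor + 1L
    cursor <- cursor + lengths[ord[i]] + margin
  }
  cbind(starts, starts + lengths - 1L)
}

#' Simulate an MSRE (HpaII/MspI) array dataset
#'
#' Site positions follow a renewal process with exponential gaps
#' (mean `gap_mean`).  A shared background hypomethylation state is drawn
#' from a two-state Markov chain along site order (spatial clustering);
#' inside planted difference regions the CVS state is set to
#' hypomethylated and the MBC state to methylated (or the reverse for the
#' 1:5 minority of reversed regions).  The undigested channel is a
#' lognormal baseline; the digested channel is the baseline times
#' `1 - d`, with `d = d_unmeth` at hypomethylated (cuttable) sites and
#' `d_meth` at methylated sites, both channels carrying multiplicative
#' lognormal noise and per-array scale factors.
#'
#' @param config parameter list from [msre_sim_config()]; site counts are
#'   `round(chrom_sites * scale)`.
#' @param n_pools pools per tissue (default 2).
#' @param seed RNG seed.
#' @return List with `signals` (a [signal_set()], channels HpaII- /
#'   HpaII+) and `truth` (`sites`: per-site states per tissue and region
#'   membership; `regions`: planted difference regions with genomic
#'   intervals and direction; `config`, `seed`).
#' @export
generate_msre_dataset <- function(config = msre_sim_config(),
                                  n_pools = 2L, seed = 1L) {
  cfg <- utils::modifyList(msre_sim_config(), config)
  set.seed(seed)
  n_per_chrom <- pmax(200L, as.integer(round(cfg$chrom_sites * cfg$scale)))
  # distribute reversed regions over chromosomes, largest first
  rev_alloc <- integer(length(n_per_chrom))
  if (cfg$n_regions_rev > 0) {
    idx <- rep(seq_along(n_per_chrom), length.out = cfg$n_regions_rev)
    rev_alloc <- tabulate(idx, nbins = length(n_per_chrom))
  }
  sites_list <- list()
  regions_list <- list()
  for (ci in seq_along(n_per_chrom)) {
    chrom <- names(cfg$chrom_sites)[ci]
    n <- n_per_chrom[ci]
    pos <- as.integer(round(cumsum(rexp(n, 1 / cfg$gap_mean)) + 1e5))
    pos <- pos + seq_len(n)            # break exact ties, keep increasing
    h <- markov_hypo_states(n, cfg$hypo_rate, cfg$run_length)
    state_cvs <- h
    state_mbc <- h
    lens <- sample(seq(cfg$region_sites[1], cfg$region_sites[2]),
                   cfg$n_regions_fwd + rev_alloc[ci], replace = TRUE)
    placed <- place_index_regions(n, lens, margin = 60L)
    types <- c(rep("CVS_hypo", cfg$n_regions_fwd),
               rep("MBC_hypo", rev_alloc[ci]))
    region_id <- integer(n)
    for (ri in seq_len(nrow(placed))) {
      ix <- placed[ri, 1]:placed[ri, 2]
      region_id[ix] <- ri
      if (types[ri] == "CVS_hypo") {
        state_cvs[ix] <- 1L
        state_mbc[ix] <- 0L
      } else {
        state_cvs[ix] <- 0L
        state_mbc[ix] <- 1L
      }
    }
    regions_list[[chrom]] <- data.frame(
      chrom = chrom,
      start = pos[placed[, 1]],
      end = pos[placed[, 2]] + 1L,
      type = types,
      start_idx = placed[, 1], end_idx = placed[, 2],
      n_sites = placed[, 2] - placed[, 1] + 1L,
      stringsAsFactors = FALSE)
    sites_list[[chrom]] <- data.frame(
      chrom = chrom, pos = pos,
      state_cvs = state_cvs, state_mbc = state_mbc,
      region_id = region_id, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites_list)
  sites$site_id <- sprintf("msp%07d", seq_len(nrow(sites)))
  rownames(sites) <- NULL
  regions <- do.call(rbind, regions_list)
  rownames(regions) <- NULL

  n <- nrow(sites)
  samples <- c(sprintf("CVS_pool%d", seq_len(n_pools)),
               sprintf("MBC_pool%d", seq_len(n_pools)))
  states <- cbind(matrix(sites$state_cvs, n, n_pools),
                  matrix(sites$state_mbc, n, n_pools))
  d <- ifelse(states == 1L, cfg$d_unmeth, cfg$d_meth)
  total <- rlnorm(n, cfg$total_mu, cfg$total_sigma)
  scl <- runif(2 * n_pools, cfg$scale_range[1], cfg$scale_range[2])
  base <- total %o% scl
  undig <- base * rlnorm(n * 2 * n_pools, 0, cfg$noise_sd)
  dig <- base * (1 - d) * rlnorm(n * 2 * n_pools, 0, cfg$noise_sd)
  colnames(undig) <- colnames(dig) <- samples
  signals <- signal_set("msre", sites[c("site_id", "chrom", "pos")],
                        ch1 = undig, ch2 = dig)
  list(signals = signals,
       truth = list(sites = sites, regions = regions,
                    config = cfg, seed = seed))
}
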