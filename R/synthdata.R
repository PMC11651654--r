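## Synthetic experiment generator. Emulates the statistical structure the
## pipeline assumes -- capture viewpoints with variable mononucleosomal
## occupancy, a power-law distance-decay contact background, planted
## fold-enriched loops, replicate structure, and the annotation files
## (peaks, DHSs, TRF peaks, CTCF motifs, TAD boundaries, CRISPRi truth
## tables) -- so every pipeline stage is testable without sequencing data.

#' Simulation configuration
#'
#' Desk-scale defaults: one 20-Mb chromosome, 60 viewpoints, 4 replicates,
#' ~850 distal pairs per viewpoint per replicate (~2e5 distal pairs total).
#' Viewpoint mononucleosomal occupancy is log-normal; per-viewpoint capture
#' strength is log-normal; other-end distances follow a truncated power law
#' `p(d) ~ d^-alpha` on `[d_min, d_max]` on both sides of the viewpoint.
#'
#' @param chrom_sizes named chromosome lengths (default one 20-Mb
#'   chromosome `chrS`).
#' @param n_viewpoints number of capture viewpoints (default 60).
#' @param vp_width viewpoint width in bp (default 1000).
#' @param n_replicates biological replicates (default 4).
#' @param pairs_per_viewpoint mean distal pairs per viewpoint per replicate
#'   (default 850).
#' @param vp_strength_sdlog log-sd of per-viewpoint capture strength
#'   (default 0.5).
#' @param occ_meanlog,occ_sdlog log-normal parameters of viewpoint
#'   mononucleosomal occupancy, per-bp depth (defaults log(10), 0.6).
#' @param decay_alpha distance-decay exponent (default 1).
#' @param d_min,d_max distance range of distal other ends (defaults 5 kb,
#'   2.5 Mb).
#' @param mono_pairs_per_vp mononucleosomal pairs per viewpoint per
#'   replicate (default 300).
#' @param other_frac fraction of additional unclassifiable (short
#'   non-convergent) pairs per replicate (default 0.05).
#' @param bg_depth mean background mononucleosomal depth outside
#'   viewpoints (default 1.5x per bp).
#' @param bg_block,bg_block_sdlog block size and log-sd of the smooth
#'   background occupancy variation (defaults 50 kb, 0.4).
#' @param bin_width analysis bin width (default 250).
#' @param peak_prob probability a viewpoint peak is detected in a given
#'   replicate's peak file (default 0.95).
#' @param planted_loops data.frame of planted loops (`viewpoint` index,
#'   `offset` signed bp from viewpoint center, `fold` enrichment >= 1), or
#'   `NULL` for a pure-background (null) experiment.
#' @param seed mandatory integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes = c(chrS = 20e6),
                       n_viewpoints = 60L, vp_width = 1000L,
                       n_replicates = 4L, pairs_per_viewpoint = 850,
                       vp_strength_sdlog = 0.5,
                       occ_meanlog = log(10), occ_sdlog = 0.6,
                       decay_alpha = 1, d_min = 5000, d_max = 2.5e6,
                       mono_pairs_per_vp = 300L, other_frac = 0.05,
                       bg_depth = 1.5, bg_block = 5e4, bg_block_sdlog = 0.4,
                       bin_width = 250L, peak_prob = 0.95,
                       planted_loops = NULL, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  cfg <- as.list(environment())
  if (!is.null(planted_loops)) {
    pl <- as.data.frame(planted_loops)
    stopifnot(all(c("viewpoint", "offset", "fold") %in% names(pl)),
              all(pl$fold >= 1))
    if (any(abs(pl$offset) > d_max))
      stop("planted target beyond the distance window")
    if (any(abs(pl$offset) < d_min))
      stop("planted target closer than d_min")
  }
  structure(cfg, class = "sim_config")
}

#' Default planted-loop layout
#'
#' Loops on evenly spread viewpoints, alternating sides, with log-spaced
#' viewpoint-target distances.
#'
#' @param n_loops number of loops (default 20).
#' @param n_viewpoints number of viewpoints in the target config.
#' @param fold fold enrichment (default 10), recycled.
#' @param d_range distance range in bp (default 20 kb - 250 kb, the
#'   regulatory-interaction distance scale).
#' @return data.frame usable as `planted_loops` in [sim_config()].
#' @export
make_planted_loops <- function(n_loops = 20L, n_viewpoints = 60L,
                               fold = 10, d_range = c(2e4, 2.5e5)) {
  vp <- round(seq(1, n_viewpoints, length.out = n_loops))
  d <- 10^seq(log10(d_range[1]), log10(d_range[2]), length.out = n_loops)
  data.frame(viewpoint = vp,
             offset = round(d) * rep_len(c(1, -1), n_loops),
             fold = rep_len(fold, n_loops))
}

## truncated power-law CDF and quantile on [d_min, d_max]
.decay_cdf <- function(d, alpha, d_min, d_max) {
  if (abs(alpha - 1) < 1e-12) log(d / d_min) / log(d_max / d_min)
  else (d^(1 - alpha) - d_min^(1 - alpha)) /
       (d_max^(1 - alpha) - d_min^(1 - alpha))
}
.decay_quantile <- function(u, alpha, d_min, d_max) {
  if (abs(alpha - 1) < 1e-12) d_min * (d_max / d_min)^u
  else (d_min^(1 - alpha) +
          u * (d_max^(1 - alpha) - d_min^(1 - alpha)))^(1 / (1 - alpha))
}

#' Simulate a complete synthetic experiment
#'
#' Generates viewpoints, a mononucleosomal fragment track, per-replicate
#' pair sets (mononucleosomal, distal with planted loops, and short
#' unclassifiable pairs), replicate peak files, DHS / TRF / CTCF-motif /
#' TAD-boundary annotations and a CRISPRi-style truth table. Deterministic
#' given the config seed. When `out_dir` is given, all components are also
#' written as plain-text files in standard formats.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with in-memory components (`viewpoints_truth`, `pairs`
#'   per-replicate list, `fragments`, `peaks` per-replicate list, `dhs`,
#'   `trf_sets`, `ctcf_motifs`, `tad_boundaries`, `crispri`, `truth`) and,
#'   when written, the file `paths`.
#' @export
simulate_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  L <- cfg$chrom_sizes[[1]]
  ch <- names(cfg$chrom_sizes)[1]
  n <- cfg$n_viewpoints
  with_seed(cfg$seed, {
    ## --- viewpoints: jittered grid with a margin wider than d_max ---
    margin <- cfg$d_max + 2e5
    span <- (L - 2 * margin) / n
    centers <- round(margin + (seq_len(n) - 0.5) * span +
                       runif(n, -0.2 * span, 0.2 * span))
    vp <- data.table::data.table(
      chrom = ch,
      start = as.integer(centers - cfg$vp_width %/% 2),
      end = as.integer(centers + cfg$vp_width %/% 2))
    vp[, `:=`(id = seq_len(n), center = centers)]
    occ <- rlnorm(n, cfg$occ_meanlog, cfg$occ_sdlog)
    strength <- rlnorm(n, 0, cfg$vp_strength_sdlog)

    ## --- planted loops ---
    planted <- NULL
    if (!is.null(cfg$planted_loops)) {
      pl <- as.data.frame(cfg$planted_loops)
      tc <- centers[pl$viewpoint] + pl$offset
      tb <- as.integer(tc %/% cfg$bin_width) * cfg$bin_width
      planted <- data.table::data.table(
        viewpoint = as.integer(pl$viewpoint), fold = pl$fold,
        target_bin_start = tb, target_bin_end = tb + cfg$bin_width,
        target_center = tb + cfg$bin_width / 2,
        distance = abs(tb + cfg$bin_width / 2 - centers[pl$viewpoint]))
      ## expected aggregate signal reads in the target bin, for
      ## coverage-adequacy assessment of recovery benchmarks
      pmass <- 0.5 * (.decay_cdf(planted$distance + cfg$bin_width / 2,
                                 cfg$decay_alpha, cfg$d_min, cfg$d_max) -
                      .decay_cdf(pmax(planted$distance - cfg$bin_width / 2,
                                      cfg$d_min),
                                 cfg$decay_alpha, cfg$d_min, cfg$d_max))
      planted[, `:=`(expected_signal_reads = cfg$n_replicates *
                       cfg$pairs_per_viewpoint *
                       strength[planted$viewpoint] * planted$fold * pmass)]
    }

    ## --- mononucleosomal fragment track ---
    n_blocks <- ceiling(L / cfg$bg_block)
    block_mult <- rlnorm(n_blocks, 0, cfg$bg_block_sdlog)
    n_bg <- round(cfg$bg_depth * L / 147)
    blk <- sample.int(n_blocks, n_bg, replace = TRUE, prob = block_mult)
    bg_pos <- pmin((blk - 1) * cfg$bg_block +
                     floor(runif(n_bg) * cfg$bg_block), L - 148)
    n_vp_frag <- round(occ * cfg$vp_width / 147)
    vp_pos <- unlist(lapply(seq_len(n), function(v)
      vp$start[v] + floor(runif(n_vp_frag[v]) * (cfg$vp_width - 147))))
    frag_start <- as.integer(sort(c(bg_pos, vp_pos)))
    fragments <- data.table::data.table(chrom = ch, start = frag_start,
                                        end = frag_start + 147L)

    ## --- per-replicate pair sets ---
    sim_distal_vp <- function(v, n_pairs) {
      if (n_pairs == 0L) return(NULL)
      pos1 <- vp$start[v] + floor(runif(n_pairs) * cfg$vp_width)
      pl_v <- if (!is.null(planted)) planted[planted$viewpoint == v] else NULL
      m <- if (is.null(pl_v)) 0L else nrow(pl_v)
      if (m) {
        mass <- 0.5 * (.decay_cdf(pl_v$distance + cfg$bin_width / 2,
                                  cfg$decay_alpha, cfg$d_min, cfg$d_max) -
                       .decay_cdf(pmax(pl_v$distance - cfg$bin_width / 2,
                                       cfg$d_min),
                                  cfg$decay_alpha, cfg$d_min, cfg$d_max))
        extra <- (pl_v$fold - 1) * mass
        probs <- c(extra, 1) / (1 + sum(extra))
        pick <- sample.int(m + 1L, n_pairs, replace = TRUE, prob = probs)
      } else pick <- rep(1L, n_pairs)
      is_bg <- pick == m + 1L | m == 0L
      pos2 <- integer(n_pairs)
      nb <- sum(is_bg)
      d <- .decay_quantile(runif(nb), cfg$decay_alpha, cfg$d_min, cfg$d_max)
      side <- sample(c(-1, 1), nb, replace = TRUE)
      pos2[is_bg] <- as.integer(round(centers[v] + side * d))
      if (any(!is_bg)) {
        tgt <- pick[!is_bg]
        pos2[!is_bg] <- as.integer(pl_v$target_bin_start[tgt] +
                                     floor(runif(sum(!is_bg)) * cfg$bin_width))
      }
      data.table::data.table(
        chrom1 = ch, pos1 = as.integer(pos1), chrom2 = ch, pos2 = pos2,
        strand1 = sample(c("+", "-"), n_pairs, replace = TRUE),
        strand2 = sample(c("+", "-"), n_pairs, replace = TRUE))
    }
    pairs_reps <- lapply(seq_len(cfg$n_replicates), function(r) {
      n_rv <- rpois(n, cfg$pairs_per_viewpoint * strength)
      distal <- data.table::rbindlist(
        lapply(seq_len(n), function(v) sim_distal_vp(v, n_rv[v])))
      ## mononucleosomal pairs at viewpoints, occupancy-weighted
      n_mono <- cfg$mono_pairs_per_vp * n
      mv <- sample.int(n, n_mono, replace = TRUE, prob = occ)
      mp1 <- vp$start[mv] + floor(runif(n_mono) * (cfg$vp_width - 200))
      msep <- sample(101:200, n_mono, replace = TRUE)
      mono <- data.table::data.table(
        chrom1 = ch, pos1 = as.integer(mp1), chrom2 = ch,
        pos2 = as.integer(mp1 + msep), strand1 = "+", strand2 = "-")
      ## short non-convergent pairs, never analyzed
      n_other <- round(cfg$other_frac * nrow(distal))
      op1 <- floor(runif(n_other) * (L - 6000))
      osep <- floor(runif(n_other, 201, 5000))
      other <- data.table::data.table(
        chrom1 = ch, pos1 = as.integer(op1), chrom2 = ch,
        pos2 = as.integer(op1 + osep),
        strand1 = sample(c("+", "-"), n_other, replace = TRUE),
        strand2 = "+")
      all <- order_mates(data.table::rbindlist(list(distal, mono, other)))
      data.table::setorder(all, chrom1, pos1, chrom2, pos2)
      all[, readID := sprintf("rep%d:%07d", r, seq_len(.N))]
      data.table::setcolorder(all, PAIR_COLS)
      all[]
    })

    ## --- replicate peak files ---
    peaks_reps <- lapply(seq_len(cfg$n_replicates), function(r) {
      present <- runif(n) < cfg$peak_prob
      pk <- vp[present, .(chrom, start = pmax(0L, start -
                  sample(0:50, sum(present), replace = TRUE)),
                end = end + sample(0:50, sum(present), replace = TRUE))]
      noise_start <- as.integer(floor(runif(3) * (L - 2000)))
      noise <- data.table::data.table(chrom = ch, start = noise_start,
                                      end = noise_start + 400L)
      pk <- rbind(pk, noise)
      data.table::setorder(pk, chrom, start)
      pk[, `:=`(name = sprintf("peak_rep%d_%d", r, seq_len(.N)),
                score = 500L, strand = ".",
                signalValue = round(rlnorm(.N, log(20), 0.5), 2),
                pValue = -1, qValue = -1, peak = -1L)]
      pk[]
    })

    ## --- DHS annotation: one per planted target + random distal sites ---
    n_planted <- if (is.null(planted)) 0L else nrow(planted)
    n_rand_dhs <- 200L - min(200L, n_planted)
    rd_pos <- floor(runif(n_rand_dhs, 5e5, L - 5e5))
    dhs_center <- c(if (n_planted) planted$target_center, rd_pos)
    dhs <- data.table::data.table(
      chrom = ch, start = as.integer(round(dhs_center - 150)),
      end = as.integer(round(dhs_center + 150)))
    data.table::setorder(dhs, chrom, start)
    dhs[, `:=`(name = sprintf("dhs_%03d", seq_len(.N)), score = 0L,
               strand = ".",
               signalValue = round(rlnorm(.N, log(400), 0.6), 2),
               pValue = -1, qValue = -1, peak = -1L)]

    ## --- TRF peak sets: each factor binds a random subset of DHSs ---
    trf_names <- paste0("TRF", 1:6)
    trf_sets <- setNames(lapply(seq_along(trf_names), function(k) {
      p_bind <- c(0.6, 0.5, 0.4, 0.3, 0.2, 0.15)[k]
      bound <- dhs[runif(.N) < p_bind,
                   .(chrom, start = start - 50L, end = end + 50L)]
      n_noise <- 30L
      np <- floor(runif(n_noise, 1e5, L - 1e5))
      noise <- data.table::data.table(chrom = ch, start = as.integer(np),
                                      end = as.integer(np + 300))
      pk <- rbind(bound, noise)
      data.table::setorder(pk, chrom, start)
      pk[, `:=`(name = sprintf("%s_%d", trf_names[k], seq_len(.N)),
                score = 0L, strand = ".",
                signalValue = round(rlnorm(.N, log(60), 0.7), 2),
                pValue = -1, qValue = -1, peak = -1L)]
      pk[]
    }), trf_names)

    ## --- CTCF motifs at a random half of DHSs, random strand ---
    with_motif <- dhs[runif(.N) < 0.5]
    ctcf_motifs <- with_motif[, .(
      chrom, start = as.integer((start + end) %/% 2 - 9L),
      end = as.integer((start + end) %/% 2 + 10L),
      name = paste0("motif_", seq_len(.N)), score = 0L,
      strand = sample(c("+", "-"), .N, replace = TRUE))]

    ## --- TAD boundaries every ~700 kb ---
    bpos <- as.integer(round(seq(1e6, L - 1e6, by = 7e5) +
                               runif(length(seq(1e6, L - 1e6, by = 7e5)),
                                     -1e5, 1e5)))
    tad_boundaries <- data.table::data.table(chrom = ch, start = bpos,
                                             end = bpos + 1L)

    ## --- CRISPRi-style truth table ---
    crispri <- NULL
    verified <- if (n_planted) data.table::data.table(
      chrom = ch,
      start = as.integer(planted$target_center - 150),
      end = as.integer(planted$target_center + 150),
      gene = paste0("gene", planted$viewpoint),
      viewpoint_id = planted$viewpoint,
      distance = planted$distance,
      label = "verified-regulatory") else NULL
    ## non-regulatory: random DHS-viewpoint pairs within 5 kb - 1 Mb,
    ## avoiding planted combinations
    nr <- data.table::rbindlist(lapply(seq_len(nrow(dhs)), function(i) {
      dc <- (dhs$start[i] + dhs$end[i]) / 2
      dvec <- abs(centers - dc)
      ok <- which(dvec >= 5000 & dvec <= 1e6)
      if (!length(ok)) return(NULL)
      take <- ok[runif(length(ok)) < 0.6]
      if (!length(take)) return(NULL)
      data.table::data.table(chrom = ch, start = dhs$start[i],
                             end = dhs$end[i], gene = paste0("gene", take),
                             viewpoint_id = take,
                             distance = round(dvec[take]),
                             label = "non-regulatory")
    }))
    if (!is.null(planted) && nrow(nr)) {
      key <- paste(planted$viewpoint, planted$target_center)
      nr <- nr[!paste(viewpoint_id, (start + end) / 2) %in% key]
    }
    crispri <- rbind(verified, nr)

    truth <- list(seed = cfg$seed, chrom_sizes = as.list(cfg$chrom_sizes),
                  viewpoints = vp, occupancy = occ, strength = strength,
                  planted = planted)

    out <- list(viewpoints_truth = vp, occupancy = occ, strength = strength,
                pairs = pairs_reps, fragments = fragments,
                peaks = peaks_reps, dhs = dhs, trf_sets = trf_sets,
                ctcf_motifs = ctcf_motifs, tad_boundaries = tad_boundaries,
                crispri = crispri, truth = truth, config = cfg)
    if (!is.null(out_dir)) out$paths <- .write_bundle(out, out_dir, cfg)
    out
  })
}

.write_bundle <- function(sim, out_dir, cfg) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, sprintf(...))
  paths <- list()
  for (r in seq_along(sim$pairs)) {
    paths[[sprintf("pairs_rep%d", r)]] <- fp("rep%d.pairs", r)
    write_pairs(sim$pairs[[r]], fp("rep%d.pairs", r), cfg$chrom_sizes)
    paths[[sprintf("peaks_rep%d", r)]] <- fp("rep%d.narrowPeak", r)
    write_bed(sim$peaks[[r]], fp("rep%d.narrowPeak", r))
  }
  paths$fragments <- fp("fragments.bed")
  write_bed(sim$fragments, paths$fragments)
  paths$dhs <- fp("dhs.narrowPeak")
  write_bed(sim$dhs, paths$dhs)
  for (nm in names(sim$trf_sets)) {
    paths[[paste0("trf_", nm)]] <- fp("trf_%s.narrowPeak", nm)
    write_bed(sim$trf_sets[[nm]], fp("trf_%s.narrowPeak", nm))
  }
  paths$ctcf_motifs <- fp("ctcf_motifs.bed")
  write_bed(sim$ctcf_motifs, paths$ctcf_motifs)
  paths$tad_boundaries <- fp("tad_boundaries.bed")
  write_bed(sim$tad_boundaries, paths$tad_boundaries)
  paths$crispri <- fp("crispri_pairs.tsv")
  data.table::fwrite(sim$crispri, paths$crispri, sep = "\t")
  paths$truth <- fp("truth.json")
  jsonlite::write_json(list(seed = sim$truth$seed,
                            chrom_sizes = sim$truth$chrom_sizes,
                            viewpoints = sim$truth$viewpoints,
                            planted = sim$truth$planted),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  paths
}

#' Simulate a feature table for contact-strength modeling
#'
#' Viewpoint-element pairs with a distance-decay target plus additive
#' contributions of designated causal factor signals and Gaussian noise;
#' decoy factor signals are independent of the target.
#'
#' @param n_pairs number of rows (default 2000).
#' @param n_candidates number of candidate factor-signal columns
#'   (default 20), named `cand01`, `cand02`, ...
#' @param causal names of causal candidates (default `"cand01"`).
#' @param effect effect size per causal feature on `log1p` signal
#'   (default 2), recycled.
#' @param noise_sd Gaussian noise sd (default 0.5).
#' @param seed integer seed.
#' @return list: `table` (data.frame with base features, candidates and
#'   `signal` target) and `truth`.
#' @export
simulate_feature_table <- function(n_pairs = 2000L, n_candidates = 20L,
                                   causal = "cand01", effect = 2,
                                   noise_sd = 0.5, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  with_seed(seed, {
    cand_names <- sprintf("cand%02d", seq_len(n_candidates))
    stopifnot(all(causal %in% cand_names))
    distance <- runif(n_pairs, 5e3, 2.5e5)
    cands <- matrix(rlnorm(n_pairs * n_candidates, 0, 1), n_pairs,
                    dimnames = list(NULL, cand_names))
    ctcf_vp <- rlnorm(n_pairs, log(20), 0.8)
    ctcf_dhs <- rlnorm(n_pairs, log(20), 0.8)
    orient <- function() {
      o <- sample(c("forward", "reverse", "none"), n_pairs, replace = TRUE,
                  prob = c(0.25, 0.25, 0.5))
      cbind(fwd = as.integer(o == "forward"),
            rev = as.integer(o == "reverse"))
    }
    ov <- orient(); od <- orient()
    eff <- rep_len(effect, length(causal))
    signal <- 5 * (distance / 5e3)^-0.7 +
      as.vector(log1p(cands[, causal, drop = FALSE]) %*% eff) +
      rnorm(n_pairs, 0, noise_sd)
    table <- data.frame(distance = distance,
                        ctcf_vp_signal = ctcf_vp,
                        ctcf_dhs_signal = ctcf_dhs,
                        vp_motif_fwd = ov[, 1], vp_motif_rev = ov[, 2],
                        dhs_motif_fwd = od[, 1], dhs_motif_rev = od[, 2],
                        cands, signal = signal)
    list(table = table,
         truth = list(causal = causal, effect = eff, noise_sd = noise_sd,
                      seed = seed))
  })
}
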