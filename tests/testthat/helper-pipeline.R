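# Shared fixtures: run the synthetic experiment through the standard
# processing chain (classify -> dedup -> consensus viewpoints -> aggregate
# -> normalize -> background fits), and match planted loops to calls.

pipeline_inputs <- function(sim) {
  cfg <- sim$config
  track <- coverage_track(sim$fragments, cfg$chrom_sizes)
  cons <- consensus_peaks(lapply(sim$peaks, function(p) p[, 1:3]),
                          min_reps = 3, merge_gap = 1000)
  distal <- lapply(sim$pairs, function(p) {
    cl <- classify_pairs(p)[pair_class == "distal"]
    data.table::setorder(cl, chrom1, pos1, chrom2, pos2)
    deduplicate_pairs(cl)
  })
  vps <- build_viewpoints(cons, track, data.table::rbindlist(distal))
  list(track = track, vps = vps, distal = distal)
}

# aggregate (summed-replicate) records + backgrounds + calls
run_aggregate_calling <- function(sim) {
  inp <- pipeline_inputs(sim)
  rec <- aggregate_contacts(data.table::rbindlist(inp$distal), inp$vps)
  nrec <- suppressMessages(normalize_contacts(rec, inp$vps, inp$track))
  bgs <- fit_backgrounds(nrec)
  list(inputs = inp, records = nrec, backgrounds = bgs,
       calls = call_aggregate(nrec, bgs))
}

# map truth viewpoint indices to built viewpoint ids by nearest center
match_truth_viewpoints <- function(vps, truth_vp) {
  built_center <- (vps$start + vps$end) / 2
  vapply(truth_vp$center, function(ctr) {
    i <- which.min(abs(built_center - ctr))
    if (abs(built_center[i] - ctr) < 2000) vps$id[i] else NA_integer_
  }, 0L)
}

# fraction of planted loops recovered by a call within one bin of the target
planted_recall <- function(calls, vps, truth, tol = 250,
                           min_expected = NULL) {
  pl <- truth$planted
  if (!is.null(min_expected))
    pl <- pl[pl$expected_signal_reads >= min_expected]
  ids <- match_truth_viewpoints(vps, truth$viewpoints)
  hit <- vapply(seq_len(nrow(pl)), function(i) {
    vpid <- ids[pl$viewpoint[i]]
    !is.na(vpid) &&
      any(calls$viewpoint_id == vpid &
            abs((calls$bin_start + calls$bin_end) / 2 -
                  pl$target_center[i]) <= tol)
  }, logical(1))
  mean(hit)
}
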