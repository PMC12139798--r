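# Shared helper for the desk-scale regime reproduction runs: one frozen
# configuration family (scaled_params defaults), varying only the coupling /
# connectivity ratios, the region, and the severing switch.

regime_run <- function(seed, R_C, R_X = 0.08, region = "shell",
                       F_sev = NULL, t_end = 18) {
  p <- scaled_params(region, R_C = R_C, R_X = R_X, t_end = t_end,
                     measure_every = 1)
  if (!is.null(F_sev)) p$F_sev <- F_sev
  tr <- tryCatch(run_simulation(p, region, seed = seed),
                 error = function(e) e)
  if (inherits(tr, "error")) {
    # a numerically aborted replicate counts as showing none of the regime
    # phenotypes; it is reported, never hidden
    message("regime run aborted (seed ", seed, "): ", conditionMessage(tr))
    return(list(trajectory = NULL, morphology = "Aborted", n_blebs = 0L,
                mechanisms = character(0), n_sever = 0L))
  }
  tracks <- track_blebs(tr)
  mech <- vapply(tracks, function(b) {
    tryCatch(as.character(classify_initiation(tr, b)),
             error = function(e) "Undetermined")
  }, "")
  list(trajectory = tr,
       morphology = classify_morphology(tr),
       n_blebs = length(tracks),
       mechanisms = mech,
       n_sever = sum(tr$events$type == "sever"))
}
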