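# Scripted stand-ins for the inner optimizer and the TMF re-evaluation,
# used to exercise the outer-loop termination logic in isolation.

mock_entries <- function(n) {
  lapply(seq_len(n), function(i) {
    e <- list(crystal = list(label = paste0("s", i)),
              u_ref = -50, w_g = 1, w_e = 1, label = paste0("s", i))
    class(e) <- "xtl_ref_entry"
    e
  })
}

mock_pots <- function() {
  free <- array(FALSE, c(2, 2, 3))
  free[1, 1, 1] <- TRUE; free[2, 2, 1] <- TRUE
  potential_set(c("X", "Y"), 1e5, 3.6, 100, free = free)
}

scripted_opts <- function(tmf_opt, tmf_re, fail_first = NULL, ...) {
  k_opt <- 0
  k_re <- 0
  failed <- FALSE
  estimation_options(
    ...,
    inner_solver = function(p_start, entries, st) {
      if (!is.null(fail_first) && !failed) {
        failed <<- TRUE
        stop(crystalfit:::lm_failure_condition(fail_first,
                                               paste0("s", fail_first),
                                               p_start))
      }
      k_opt <<- k_opt + 1
      list(p_hat = p_start + k_opt,
           tmf_dyn = tmf_opt[min(k_opt, length(tmf_opt))])
    },
    reevaluator = function(p) {
      k_re <<- k_re + 1
      tmf_re[min(k_re, length(tmf_re))]
    })
}
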