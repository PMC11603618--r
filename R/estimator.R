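#' Estimation options
#'
#' Settings of the outer parameter-estimation loop.
#'
#' @param reinit_limit Maximum number of re-initializations (B6).
#' @param insufficient_decrease Relative decrease of the re-evaluated
#'   TMF between successive optimization attempts below which the fit
#'   terminates (B4); the solution surface is then flat near the
#'   optimum.
#' @param b3_rel,b3_abs Tolerances declaring the re-evaluated TMF
#'   unchanged from the optimizer's final value (B3).
#' @param lower,upper Parameter bounds (default non-negative,
#'   unbounded above).
#' @param sobol_span Multiplicative half-span of the default Sobol'
#'   sampling box around the starting magnitudes (default 10: two
#'   decades total). Always user-visible; sampling bounds must be
#'   finite.
#' @param sobol_skip Initial Sobol' points skipped.
#' @param cluster_tmf_rel,cluster_par_tol Clustering tolerances:
#'   relative TMF agreement and scaled-parameter infinity-norm.
#' @param inner_maxiter Iteration cap of the inner least-squares solver.
#' @param workers Worker count of the scheduling contract. Execution is
#'   organized so results are identical to serial processing
#'   regardless of this value.
#' @param lm_opts [latmin_options()] used for every lattice
#'   minimization.
#' @param denominator Energy-residual convention (see
#'   [energy_residual()]).
#' @param inner_solver,reevaluator Optional overrides of the inner
#'   optimizer and the reference-geometry TMF re-evaluation (used to
#'   exercise the termination logic with scripted merit sequences).
#' @return List of settings.
#' @export
estimation_options <- function(reinit_limit = 10,
                               insufficient_decrease = 1e-3,
                               b3_rel = 1e-8, b3_abs = 1e-14,
                               lower = 0, upper = Inf,
                               sobol_span = 10, sobol_skip = 1,
                               cluster_tmf_rel = 1e-3,
                               cluster_par_tol = 1e-2,
                               inner_maxiter = 50, workers = 1,
                               lm_opts = latmin_options(),
                               denominator = "abs",
                               inner_solver = NULL, reevaluator = NULL) {
  stopifnot(reinit_limit >= 1, insufficient_decrease > 0, b3_rel > 0)
  list(reinit_limit = reinit_limit,
       insufficient_decrease = insufficient_decrease,
       b3_rel = b3_rel, b3_abs = b3_abs, lower = lower, upper = upper,
       sobol_span = sobol_span, sobol_skip = sobol_skip,
       cluster_tmf_rel = cluster_tmf_rel,
       cluster_par_tol = cluster_par_tol,
       inner_maxiter = inner_maxiter, workers = workers,
       lm_opts = lm_opts, denominator = denominator,
       inner_solver = inner_solver, reevaluator = reevaluator)
}

#' Termination decision of the outer loop
#'
#' Applies, in order: B3 (re-evaluated TMF unchanged from the
#' optimizer's final value — accept), B5 (re-evaluated TMF increased
#' over the previous attempt — accept the previous estimates), B4
#' (decreased but insufficiently — accept the current estimates), B6
#' (re-initialization limit reached), else B1 (re-initialize and
#' optimize again). B4 and B5 are skipped on the first attempt, where
#' no previous re-evaluation exists.
#'
#' @param tmf_opt Final TMF reported by the inner optimizer (dynamic
#'   starting points).
#' @param tmf_re TMF re-evaluated from the original reference
#'   geometries.
#' @param tmf_prev Previous attempt's re-evaluated TMF (NULL on the
#'   first attempt).
#' @param reinits Number of re-initializations performed so far.
#' @param opts [estimation_options()].
#' @return One of `"B3"`, `"B4"`, `"B5"`, `"B6"`, `"B1"`.
#' @export
decide_termination <- function(tmf_opt, tmf_re, tmf_prev, reinits, opts) {
  if (abs(tmf_re - tmf_opt) <=
      max(opts$b3_rel * max(abs(tmf_re), abs(tmf_opt)), opts$b3_abs))
    return("B3")
  if (!is.null(tmf_prev)) {
    if (tmf_re > tmf_prev) return("B5")
    if ((tmf_prev - tmf_re) < opts$insufficient_decrease * tmf_prev)
      return("B4")
  }
  if (reinits >= opts$reinit_limit) return("B6")
  "B1"
}

#' Structure processing order by estimated cost
#'
#' Stable descending sort of per-structure cost estimates: the most
#' expensive minimizations are dispatched first so a pool of workers
#' idles least. Ties keep input order. The execution contract is that
#' results are identical to serial processing whatever the schedule or
#' worker count.
#'
#' @param costs Numeric cost estimates (first iteration: use a
#'   constant vector to keep input order).
#' @return Integer permutation of `seq_along(costs)`.
#' @export
schedule_structures <- function(costs) {
  order(-costs, seq_along(costs))
}

# condition used to abort the inner solver on a lattice-minimization
# failure (D3)
lm_failure_condition <- function(index, label, p) {
  structure(class = c("xtl_lm_failure", "error", "condition"),
            list(message = sprintf(
                   "lattice minimization failed for structure '%s'", label),
                 call = NULL, index = index, label = label, p = p))
}

#' Local parameter estimation with dynamic starting points
#'
#' Minimizes the total merit function from one starting parameter
#' vector. The inner solver is a bound-constrained nonlinear
#' least-squares iteration on the weighted residual vector with the
#' analytic Jacobian. Lattice minimizations start from the reference
#' geometries on the first TMF evaluation and thereafter from the
#' previous evaluation's optima (dynamic starting points). On solver
#' termination the TMF is re-evaluated from the original reference
#' geometries and the termination criteria of [decide_termination()]
#' applied; otherwise the solver is re-initialized at the current
#' estimates. A lattice-minimization failure removes the offending
#' structure and restarts from the last successful iterate; removed
#' structures are reintroduced for one final optimization and
#' re-evaluation before reporting.
#'
#' @param p0 Starting free-parameter vector (order of
#'   [free_param_table()]).
#' @param entries List of [reference_entry()] training structures.
#' @param pots `xtl_potentials` template (holds fixed parameters, free
#'   flags and combining mode).
#' @param opts [estimation_options()].
#' @return An object of class `xtl_estimation`: list with `p_hat`,
#'   `TMF_final` (re-evaluated), `status` (`"B3_converged"`,
#'   `"B4_slow_decrease"`, `"B5_increase"`, `"B6_reinit_limit"`,
#'   `"failed"`), `removed_history`, `trace` (one row per TMF
#'   re-evaluation), `attempts`, `lm_calls`, `per_structure`.
#' @export
run_local <- function(p0, entries, pots, opts = estimation_options()) {
  ns <- length(entries)
  stopifnot(ns >= 1)
  tab <- free_param_table(pots)
  np <- nrow(tab)
  stopifnot(length(p0) == np)
  p_scale <- pmax(abs(p0), 1e-12)
  lower <- rep_len(opts$lower, np)
  upper <- rep_len(opts$upper, np)

  st <- new.env(parent = emptyenv())
  st$starts <- lapply(entries, function(e) e$crystal)  # dynamic starting pts
  st$costs <- rep(1, ns)
  st$active <- rep(TRUE, ns)
  st$cache <- NULL
  st$last_ok_p <- p0
  st$lm_calls0 <- lm_call_count()
  st$trace <- list()
  removed_history <- list()

  eval_residuals <- function(p, starts, active_idx, want_jac) {
    # evaluate every active structure (scheduled order), assemble in
    # input order; returns wres, per-structure records, optionally jac
    ord <- active_idx[schedule_structures(st$costs[active_idx])]
    recs <- vector("list", ns)
    for (i in ord) {
      r <- evaluate_structure(entries[[i]], pots_at(p), starts[[i]],
                              opts$lm_opts, opts$denominator,
                              want_sensitivity = want_jac)
      if (!r$ok) stop(lm_failure_condition(i, entries[[i]]$label, p))
      st$costs[i] <- r$lm$n_energy
      recs[[i]] <- r
    }
    wres <- unlist(lapply(active_idx, function(i) recs[[i]]$wres))
    jac <- if (want_jac)
      do.call(rbind, lapply(active_idx, function(i) recs[[i]]$jac))
    list(wres = wres, jac = jac, recs = recs,
         tmf = sum(vapply(active_idx, function(i) recs[[i]]$MF, 0)))
  }

  pots_at <- function(p) set_params(pots, p)

  inner_solve <- function(p_start, active_idx) {
    if (!is.null(opts$inner_solver))
      return(opts$inner_solver(p_start, entries[active_idx], st))
    q0 <- p_start / p_scale
    st$cache <- NULL
    fn_q <- function(q) {
      p <- q * p_scale
      if (!is.null(st$cache) && isTRUE(all(q == st$cache$q)))
        return(st$cache$wres)
      ev <- eval_residuals(p, st$starts, active_idx, want_jac = TRUE)
      # dynamic starting points: warm-start the next evaluation
      for (i in active_idx) st$starts[[i]] <- ev$recs[[i]]$lm$crystal
      # the inner solver mutates its parameter vector in place; cache a
      # genuine copy or the key would alias the live vector
      st$cache <- list(q = q + 0, wres = ev$wres, jac = ev$jac,
                       tmf = ev$tmf, recs = ev$recs)
      st$last_ok_p <- p
      ev$wres
    }
    jac_q <- function(q) {
      if (is.null(st$cache) || !isTRUE(all(q == st$cache$q))) fn_q(q)
      # chain rule p = q * p_scale; no lattice minimizations here
      sweep(st$cache$jac, 2, p_scale, "*")
    }
    ctrl <- minpack.lm::nls.lm.control(maxiter = opts$inner_maxiter,
                                       ftol = 1e-15, ptol = 1e-15,
                                       gtol = 0)
    sol <- minpack.lm::nls.lm(par = q0, lower = lower / p_scale,
                              upper = upper / p_scale,
                              fn = fn_q, jac = jac_q, control = ctrl)
    p_hat <- as.numeric(sol$par) * p_scale
    # make sure the cache corresponds to p_hat
    fn_q(as.numeric(sol$par))
    list(p_hat = p_hat, tmf_dyn = st$cache$tmf)
  }

  reevaluate <- function(p, active_idx) {
    if (!is.null(opts$reevaluator)) return(opts$reevaluator(p))
    ev <- eval_residuals(p, lapply(entries, function(e) e$crystal),
                         active_idx, want_jac = FALSE)
    ev$tmf
  }

  finish <- function(p_hat, tmf, status, per = NULL) {
    structure(list(p_hat = stats::setNames(p_hat, tab$name),
                   TMF_final = tmf, status = status,
                   removed_history = removed_history,
                   trace = do.call(rbind, st$trace),
                   attempts = length(st$trace),
                   lm_calls = lm_call_count() - st$lm_calls0,
                   per_structure = per),
              class = "xtl_estimation")
  }

  run_phase <- function(p_start, active, allow_reinit = TRUE) {
    # one complete B1-B6 loop over the active set; returns result or an
    # lm-failure condition
    tmf_prev <- NULL
    p_prev <- NULL
    reinits <- 0L
    p_cur <- p_start
    repeat {
      sol <- tryCatch(inner_solve(p_cur, active),
                      xtl_lm_failure = function(e) e)
      if (inherits(sol, "xtl_lm_failure")) return(sol)
      tmf_re <- tryCatch(reevaluate(sol$p_hat, active),
                         xtl_lm_failure = function(e) e)
      if (inherits(tmf_re, "xtl_lm_failure")) return(tmf_re)
      dec <- decide_termination(sol$tmf_dyn, tmf_re, tmf_prev, reinits, opts)
      st$trace[[length(st$trace) + 1]] <-
        data.frame(attempt = length(st$trace) + 1,
                   tmf_dyn = sol$tmf_dyn, tmf_re = tmf_re,
                   decision = dec, n_active = length(active))
      if (dec == "B3") return(list(p = sol$p_hat, tmf = tmf_re, code = "B3"))
      if (dec == "B4") return(list(p = sol$p_hat, tmf = tmf_re, code = "B4"))
      if (dec == "B5") return(list(p = p_prev, tmf = tmf_prev, code = "B5"))
      if (dec == "B6" || !allow_reinit) {
        if (!is.null(tmf_prev) && tmf_prev < tmf_re)
          return(list(p = p_prev, tmf = tmf_prev, code = "B6"))
        return(list(p = sol$p_hat, tmf = tmf_re, code = "B6"))
      }
      # B1: reinitialize; dynamic starting points reset to references
      reinits <- reinits + 1L
      tmf_prev <- tmf_re
      p_prev <- sol$p_hat
      p_cur <- sol$p_hat
      st$starts <- lapply(entries, function(e) e$crystal)
    }
  }

  status_of <- function(code) switch(code,
    B3 = "B3_converged", B4 = "B4_slow_decrease", B5 = "B5_increase",
    B6 = "B6_reinit_limit")

  p_cur <- p0
  repeat {
    active <- which(st$active)
    if (length(active) == 0)
      return(finish(st$last_ok_p, NA_real_, "failed"))
    out <- run_phase(p_cur, active)
    if (inherits(out, "xtl_lm_failure")) {
      # D3: remove the failing structure, restart from the last iterate
      st$active[out$index] <- FALSE
      removed_history[[length(removed_history) + 1]] <-
        list(label = out$label, index = out$index, phase = "removed")
      p_cur <- st$last_ok_p
      next
    }
    status <- status_of(out$code)
    p_hat <- out$p
    tmf_final <- out$tmf
    break
  }

  # A3-A5: reintroduce removed structures for one final optimization and
  # re-evaluation, reported without further iteration
  if (any(!st$active)) {
    for (i in which(!st$active))
      removed_history[[length(removed_history) + 1]] <-
        list(label = entries[[i]]$label, index = i, phase = "reintroduced")
    st$active[] <- TRUE
    st$starts <- lapply(entries, function(e) e$crystal)
    fin <- run_phase(p_hat, seq_len(ns), allow_reinit = FALSE)
    if (!inherits(fin, "xtl_lm_failure")) {
      p_hat <- fin$p
      tmf_final <- fin$tmf
      status <- status_of(fin$code)
    } else {
      status <- "failed"
    }
  }

  per <- if (!is.null(st$cache))
    data.frame(label = vapply(entries, function(e) e$label, ""),
               MF = vapply(seq_len(ns), function(i) {
                 r <- st$cache$recs[[i]]
                 if (!is.null(r) && r$ok) r$MF else NA_real_
               }, 0))
  finish(p_hat, tmf_final, status, per)
}

#' @export
print.xtl_estimation <- function(x, ...) {
  cat(sprintf("<estimation: status=%s TMF=%.6e attempts=%d lm_calls=%d>\n",
              x$status, x$TMF_final, x$attempts, x$lm_calls))
  if (length(x$p_hat)) {
    cat("  p_hat:\n")
    print(signif(x$p_hat, 6))
  }
  invisible(x)
}

#' Multistart parameter estimation from Sobol' points
#'
#' Runs [run_local()] independently from each Sobol' starting vector
#' and clusters the non-failed results into distinct minima by
#' agreement of the re-evaluated TMF (relative tolerance) and of the
#' scaled parameters (infinity norm). Starts are processed serially in
#' point order so results are reproducible; the per-start problems are
#' independent by construction (the scheduling contract of
#' [schedule_structures()]).
#'
#' @param n_points Number of Sobol' starting points.
#' @param entries Training set (list of [reference_entry()]).
#' @param pots `xtl_potentials` template; its current free-parameter
#'   values center the default sampling box.
#' @param opts [estimation_options()].
#' @param sobol_bounds Optional 2 x NP matrix (rows: lower, upper) of
#'   finite sampling bounds; default spans `sobol_span` above and below
#'   the template values.
#' @return List with `runs` (all [run_local()] results), `starts`,
#'   `clusters` (list of index vectors, best first), `best` (the
#'   lowest-TMF run), `p_hat`, `TMF`.
#' @export
run_multistart <- function(n_points, entries, pots,
                           opts = estimation_options(),
                           sobol_bounds = NULL) {
  stopifnot(n_points >= 1)
  p_ref <- get_params(pots)
  if (is.null(sobol_bounds))
    sobol_bounds <- rbind(p_ref / opts$sobol_span, p_ref * opts$sobol_span)
  starts <- sobol_starts(n_points, sobol_bounds[1, ], sobol_bounds[2, ],
                         skip = opts$sobol_skip)
  runs <- vector("list", n_points)
  for (k in seq_len(n_points)) {
    runs[[k]] <- tryCatch(run_local(starts[k, ], entries, pots, opts),
                          error = function(e)
                            structure(list(p_hat = starts[k, ],
                                           TMF_final = NA_real_,
                                           status = "failed",
                                           message = conditionMessage(e)),
                                      class = "xtl_estimation"))
  }
  cl <- cluster_minima(runs, opts)
  best_run <- if (length(cl$clusters))
    runs[[cl$clusters[[1]][1]]] else NULL
  list(runs = runs, starts = starts, clusters = cl$clusters,
       best = best_run,
       p_hat = if (!is.null(best_run)) best_run$p_hat else NULL,
       TMF = if (!is.null(best_run)) best_run$TMF_final else NA_real_)
}

#' Cluster multistart results into distinct minima
#'
#' Two results belong to the same minimum when their re-evaluated TMF
#' values agree within a relative tolerance and their parameters agree
#' within an infinity-norm tolerance after scaling. Clusters partition
#' the non-failed runs and are ordered by increasing TMF.
#'
#' @param runs List of [run_local()] results.
#' @param opts [estimation_options()] (clustering tolerances).
#' @return List with `clusters`: list of integer index vectors.
#' @export
cluster_minima <- function(runs, opts = estimation_options()) {
  ok <- which(vapply(runs, function(r)
    r$status != "failed" && is.finite(r$TMF_final), TRUE))
  ok <- ok[order(vapply(ok, function(i) runs[[i]]$TMF_final, 0))]
  clusters <- list()
  for (i in ok) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      j <- clusters[[ci]][1]
      ti <- runs[[i]]$TMF_final; tj <- runs[[j]]$TMF_final
      tmf_ok <- abs(ti - tj) <=
        max(opts$cluster_tmf_rel * max(abs(ti), abs(tj)), 1e-14)
      sc <- pmax(abs(runs[[j]]$p_hat), 1e-12)
      par_ok <- max(abs(runs[[i]]$p_hat - runs[[j]]$p_hat) / sc) <=
        opts$cluster_par_tol
      if (tmf_ok && par_ok) {
        clusters[[ci]] <- c(clusters[[ci]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1]] <- i
  }
  list(clusters = clusters)
}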