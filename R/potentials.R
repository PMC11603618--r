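#' Buckingham pair potential value
#'
#' `phi(r) = A exp(-B r) - C / r^6` for an interatomic distance `r > 0`.
#'
#' @param r Distance in Angstrom (vectorized).
#' @param A Repulsion prefactor, kJ/mol.
#' @param B Repulsion steepness, 1/Angstrom.
#' @param C Dispersion coefficient, kJ mol^-1 Angstrom^6.
#' @return Energy in kJ/mol.
#' @export
buckingham_pair <- function(r, A, B, C) {
  if (any(r <= 0)) stop("buckingham_pair: r must be positive", call. = FALSE)
  A * exp(-B * r) - C / r^6
}

#' Combining rules for heteroatomic Buckingham parameters
#'
#' Geometric mean for `A` and `C`; arithmetic mean of the inverse for `B`
#' (harmonic mean of `B`).
#'
#' @param pi_,pj_ Numeric length-3 vectors `c(A, B, C)` of the two
#'   homoatomic interactions.
#' @return Numeric length-3 vector `c(A, B, C)` of the cross interaction.
#' @export
combine_cross <- function(pi_, pj_) {
  if (pi_[2] <= 0 || pj_[2] <= 0)
    stop("combining rules require positive homoatomic B", call. = FALSE)
  c(sqrt(pi_[1] * pj_[1]),
    2 / (1 / pi_[2] + 1 / pj_[2]),
    sqrt(pi_[3] * pj_[3]))
}

#' Chain factors of the combining rules
#'
#' Derivative of a cross parameter with respect to one of its homoatomic
#' parents: `dA_ij/dA_ii = 0.5 sqrt(A_jj / A_ii)` (likewise for `C`),
#' and `dB_ij/dB_ii = 0.5 (B_ij / B_ii)^2` from the harmonic-mean rule.
#' For `i == j` the factor is 1.
#'
#' @param comp `"A"`, `"B"` or `"C"`.
#' @param p_ii Parent homoatomic value (the one differentiated with
#'   respect to).
#' @param p_jj The other homoatomic value.
#' @return Scalar chain factor.
#' @export
combine_chain_factor <- function(comp, p_ii, p_jj) {
  if (comp %in% c("A", "C")) {
    if (p_ii == 0 && p_jj == 0) return(0)
    if (p_ii == 0)
      stop("combining-rule derivative singular at zero homoatomic ", comp,
           call. = FALSE)
    return(0.5 * sqrt(p_jj / p_ii))
  }
  bij <- 2 / (1 / p_ii + 1 / p_jj)
  0.5 * (bij / p_ii)^2
}

#' Potential set
#'
#' A symmetric table of Buckingham parameters per atom-type pair, with
#' free/fixed flags and bounds. In `"explicit"` mode every pair is an
#' independent interaction; in `"combine"` mode only homoatomic entries
#' are primary and cross pairs are derived by [combine_cross()] at
#' evaluation time (their free flags must be FALSE).
#'
#' @param types Character vector of atom-type labels.
#' @param A,B,C Symmetric `T x T` matrices (or scalars recycled) of
#'   parameters in kJ/mol, 1/Angstrom, kJ mol^-1 Angstrom^6.
#' @param free Logical `T x T x 3` array (dimnames comp = A, B, C)
#'   flagging which parameters are estimated; only the upper triangle
#'   (`i <= j`) is read. Default: all fixed.
#' @param lower,upper Bounds applied to every free parameter (default
#'   `[0, Inf)`).
#' @param mode `"explicit"` or `"combine"`.
#' @return An object of class `xtl_potentials`.
#' @export
potential_set <- function(types, A, B, C, free = NULL,
                          lower = 0, upper = Inf,
                          mode = c("explicit", "combine")) {
  mode <- match.arg(mode)
  nt <- length(types)
  as_mat <- function(x) {
    if (length(x) == 1) matrix(x, nt, nt)
    else matrix(as.numeric(x), nt, nt)
  }
  A <- as_mat(A); B <- as_mat(B); C <- as_mat(C)
  for (M in list(A, B, C))
    if (max(abs(M - t(M))) > 0) stop("parameter matrices must be symmetric",
                                     call. = FALSE)
  if (any(B <= 0)) stop("B parameters must be positive", call. = FALSE)
  if (is.null(free)) free <- array(FALSE, c(nt, nt, 3))
  dimnames(free) <- list(types, types, c("A", "B", "C"))
  if (mode == "combine") {
    for (cmp in 1:3) {
      fr <- free[, , cmp]
      if (any(fr[upper.tri(fr)]))
        stop("in combine mode only homoatomic parameters may be free",
             call. = FALSE)
    }
  }
  structure(list(types = types, A = A, B = B, C = C, free = free,
                 lower = lower, upper = upper, mode = mode),
            class = "xtl_potentials")
}

#' @export
print.xtl_potentials <- function(x, ...) {
  cat(sprintf("<potential set: %d types (%s), mode %s, %d free parameters>\n",
              length(x$types), paste(x$types, collapse = ", "), x$mode,
              nrow(free_param_table(x))))
  invisible(x)
}

# Effective (evaluation) parameter matrices: in combine mode, cross pairs
# are regenerated from the homoatomic diagonal.
effective_params <- function(pots) {
  if (pots$mode == "explicit")
    return(list(A = pots$A, B = pots$B, C = pots$C))
  nt <- length(pots$types)
  A <- pots$A; B <- pots$B; C <- pots$C
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (i == j) next
    pc <- combine_cross(c(A[i, i], B[i, i], C[i, i]),
                        c(A[j, j], B[j, j], C[j, j]))
    A[i, j] <- pc[1]; B[i, j] <- pc[2]; C[i, j] <- pc[3]
  }
  list(A = A, B = B, C = C)
}

#' Table of free parameters
#'
#' One row per estimated parameter: type indices `i <= j`, component,
#' a readable name, current value and bounds. The row order defines the
#' parameter-vector ordering used throughout the estimation.
#'
#' @param pots An `xtl_potentials`.
#' @return A data.frame.
#' @export
free_param_table <- function(pots) {
  nt <- length(pots$types)
  comp <- c("A", "B", "C")
  rows <- list()
  for (ci in 1:3) {
    Mv <- pots[[comp[ci]]]
    for (i in seq_len(nt)) for (j in i:nt) {
      if (!isTRUE(pots$free[i, j, ci])) next
      rows[[length(rows) + 1]] <- data.frame(
        i = i, j = j, comp = comp[ci],
        name = sprintf("%s_%s.%s", comp[ci], pots$types[i], pots$types[j]),
        value = Mv[i, j], lower = pots$lower, upper = pots$upper,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(i = integer(), j = integer(), comp = character(),
                      name = character(), value = numeric(),
                      lower = numeric(), upper = numeric()))
  do.call(rbind, rows)
}

#' Get the free-parameter vector
#' @param pots An `xtl_potentials`.
#' @return Named numeric vector in [free_param_table()] order.
#' @export
get_params <- function(pots) {
  tab <- free_param_table(pots)
  stats::setNames(tab$value, tab$name)
}

#' Set the free-parameter vector
#' @param pots An `xtl_potentials`.
#' @param p Numeric vector in [free_param_table()] order.
#' @return The updated `xtl_potentials`.
#' @export
set_params <- function(pots, p) {
  tab <- free_param_table(pots)
  stopifnot(length(p) == nrow(tab))
  for (r in seq_len(nrow(tab))) {
    cmp <- tab$comp[r]
    pots[[cmp]][tab$i[r], tab$j[r]] <- p[r]
    pots[[cmp]][tab$j[r], tab$i[r]] <- p[r]
  }
  pots
}

# Map raw per-pair derivatives (w.r.t. every (i<=j, comp) effective
# parameter) onto the free-parameter vector, folding in combining-rule
# chain factors in combine mode. `raw` is a matrix with one column per
# (pair, comp) in the canonical order produced by pair_comp_index().
chain_to_free <- function(pots, raw_dU, raw_cross = NULL) {
  tab <- free_param_table(pots)
  np <- nrow(tab)
  idx <- pair_comp_index(length(pots$types))
  dU <- numeric(np)
  cross <- if (!is.null(raw_cross)) matrix(0, nrow(raw_cross), np) else NULL
  for (r in seq_len(np)) {
    ti <- tab$i[r]; tj <- tab$j[r]; cmp <- tab$comp[r]
    if (pots$mode == "explicit" || ti != tj) {
      k <- idx[[cmp]][ti, tj]
      dU[r] <- raw_dU[k]
      if (!is.null(cross)) cross[, r] <- raw_cross[, k]
    } else {
      # combine mode, homoatomic parent: sum over all pairs involving ti
      nt <- length(pots$types)
      for (j2 in seq_len(nt)) {
        a <- min(ti, j2); b <- max(ti, j2)
        k <- idx[[cmp]][a, b]
        fac <- if (j2 == ti) 1 else
          combine_chain_factor(cmp, pots[[cmp]][ti, ti], pots[[cmp]][j2, j2])
        dU[r] <- dU[r] + fac * raw_dU[k]
        if (!is.null(cross)) cross[, r] <- cross[, r] + fac * raw_cross[, k]
      }
    }
  }
  list(dU = stats::setNames(dU, tab$name), cross = cross)
}

# Canonical (pair, comp) column indexing for the raw derivative outputs
# of the energy core: columns are ordered A-pairs, B-pairs, C-pairs, with
# pairs enumerated i <= j row-major.
pair_comp_index <- function(nt) {
  npair <- nt * (nt + 1) / 2
  P <- matrix(NA_integer_, nt, nt)
  k <- 0L
  for (i in seq_len(nt)) for (j in i:nt) {
    k <- k + 1L
    P[i, j] <- k; P[j, i] <- k
  }
  list(A = P, B = P + npair, C = P + 2L * npair, npair = npair)
}

#' Count fitted force-field parameters for a set of atom types
#'
#' Applies the fitting conventions used throughout: two parameters (A
#' and C) per pair of atom types present, with B always fixed; the
#' dispersion C fixed to zero (not fitted) for every pair involving a
#' polarized hydrogen type; and pairs with no reference contacts
#' excluded entirely.
#'
#' @param types Character vector of atom types (e.g.
#'   `c("C","H","N","O")`).
#' @param hp_types Types whose pairs carry no free dispersion term
#'   (default `"Hp"`).
#' @param absent_pairs List of length-2 character vectors of type pairs
#'   excluded from fitting (default: sulfur-chlorine).
#' @return Integer number of fitted parameters.
#' @export
count_fit_parameters <- function(types, hp_types = "Hp",
                                 absent_pairs = list(c("S", "Cl"))) {
  nt <- length(types)
  n <- 0L
  for (i in seq_len(nt)) for (j in i:nt) {
    pair <- c(types[i], types[j])
    absent <- any(vapply(absent_pairs, function(ap)
      setequal(ap, pair) || all(sort(ap) == sort(pair)), TRUE))
    if (absent) next
    n <- n + 1L                                   # A
    if (!any(pair %in% hp_types)) n <- n + 1L     # C
  }
  n
}
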