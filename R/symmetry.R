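#' Symmetry operator
#'
#' A space-group operation in the fractional basis: `f -> R f + t`.
#' Rotation parts are integer matrices with determinant +1 or -1;
#' translations are reduced to the half-open interval `[0, 1)`.
#'
#' @param rotation 3x3 integer matrix acting on fractional column vectors.
#' @param translation Length-3 fractional translation.
#' @return An object of class `xtl_symop`.
#' @export
symop <- function(rotation, translation = c(0, 0, 0)) {
  R <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(R - round(R))) > 1e-10)
    stop("symmetry rotation must be an integer matrix in the fractional basis",
         call. = FALSE)
  R <- round(R)
  dt <- round(det(R))
  if (!dt %in% c(-1, 1))
    stop("symmetry rotation determinant must be +1 or -1", call. = FALSE)
  t <- as.numeric(translation) %% 1
  structure(list(R = R, t = t), class = "xtl_symop")
}

#' @export
print.xtl_symop <- function(x, ...) {
  cat("<symop>", symop_to_string(x), "\n")
  invisible(x)
}

symop_identity <- function() symop(diag(3), c(0, 0, 0))

is_identity_op <- function(op) {
  all(op$R == diag(3)) && all(abs(op$t) < 1e-10)
}

apply_symop <- function(op, f) {
  # f: length-3 vector or 3-column matrix of fractional coordinates
  if (is.matrix(f)) t(op$R %*% t(f) + op$t) else as.numeric(op$R %*% f + op$t)
}

#' Symmetry operators for a handful of common space groups
#'
#' Supported settings: `"P1"`, `"P-1"`, `"P21"` (unique axis b),
#' `"P21/c"`.
#'
#' @param name Space-group symbol.
#' @return List of `xtl_symop`.
#' @export
sg_ops <- function(name) {
  id <- symop_identity()
  switch(name,
    "P1"  = list(id),
    "P-1" = list(id, symop(-diag(3))),
    "P21" = list(id, symop(diag(c(-1, 1, -1)), c(0, 0.5, 0))),
    "P21/c" = list(id,
                   symop(diag(c(-1, 1, -1)), c(0, 0.5, 0.5)),
                   symop(-diag(3)),
                   symop(diag(c(1, -1, 1)), c(0, 0.5, 0.5))),
    stop("unsupported space group: ", name))
}

# Crystal system compatible with a space-group symbol (for toy generation).
sg_system <- function(name) {
  switch(name,
    "P1" = "triclinic", "P-1" = "triclinic",
    "P21" = "monoclinic", "P21/c" = "monoclinic",
    stop("unsupported space group: ", name))
}

# Parse a SHELX-style SYMM string such as "-X, 1/2+Y, 1/2-Z" into a symop.
parse_symm <- function(s) {
  parts <- strsplit(toupper(gsub("[[:space:]]", "", s)), ",")[[1]]
  if (length(parts) != 3) stop("malformed SYMM record: ", s, call. = FALSE)
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in seq_len(3)) {
    expr <- parts[i]
    # tokenize signed terms
    expr <- gsub("-", "+-", expr)
    toks <- strsplit(expr, "\\+")[[1]]
    toks <- toks[nzchar(toks)]
    for (tok in toks) {
      sign <- 1
      if (startsWith(tok, "-")) { sign <- -1; tok <- substring(tok, 2) }
      if (tok %in% c("X", "Y", "Z")) {
        R[i, match(tok, c("X", "Y", "Z"))] <-
          R[i, match(tok, c("X", "Y", "Z"))] + sign
      } else if (grepl("^[0-9.]+/[0-9.]+$", tok)) {
        nd <- as.numeric(strsplit(tok, "/")[[1]])
        t[i] <- t[i] + sign * nd[1] / nd[2]
      } else if (grepl("^[0-9.]+$", tok)) {
        t[i] <- t[i] + sign * as.numeric(tok)
      } else if (grepl("^[0-9.]+\\*?[XYZ]$", tok) || grepl("^[0-9.]+/[0-9.]+\\*?[XYZ]$", tok)) {
        ax <- substring(tok, nchar(tok))
        coef <- sub("\\*?[XYZ]$", "", tok)
        if (grepl("/", coef)) {
          nd <- as.numeric(strsplit(coef, "/")[[1]]); coef <- nd[1] / nd[2]
        } else coef <- as.numeric(coef)
        R[i, match(ax, c("X", "Y", "Z"))] <-
          R[i, match(ax, c("X", "Y", "Z"))] + sign * coef
      } else stop("cannot parse SYMM token: ", tok, call. = FALSE)
    }
  }
  symop(R, t)
}

symop_to_string <- function(op) {
  axes <- c("X", "Y", "Z")
  row_str <- function(i) {
    s <- ""
    for (j in 1:3) {
      r <- op$R[i, j]
      if (r == 0) next
      sgn <- if (r > 0) (if (nzchar(s)) "+" else "") else "-"
      coef <- if (abs(r) == 1) "" else paste0(abs(r), "*")
      s <- paste0(s, sgn, coef, axes[j])
    }
    if (abs(op$t[i]) > 1e-10) {
      fr <- frac_string(op$t[i])
      s <- paste0(fr, if (startsWith(s, "-")) "" else "+", s)
    }
    s
  }
  paste(vapply(1:3, row_str, ""), collapse = ", ")
}

frac_string <- function(x) {
  for (den in c(2, 3, 4, 6)) {
    num <- x * den
    if (abs(num - round(num)) < 1e-9) return(sprintf("%d/%d", round(num), den))
  }
  sprintf("%.6f", x)
}
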