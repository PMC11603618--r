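#' Read a SHELX .res crystal structure file
#'
#' Supports the CELL / ZERR / LATT / SYMM / SFAC dialect with fractional
#' atom records. The LATT code (centering and centrosymmetry) and SYMM
#' records are expanded into an explicit operator list; elements are
#' taken from the SFAC index of each atom record (or the label prefix
#' when no SFAC is present). Charges and atom types are not part of the
#' format; they are attached by [read_manifest()].
#'
#' @param path File path.
#' @return An `xtl_crystal` whose molecules are single placeholder
#'   "molecules" per atom record (re-partitioned by the manifest), with
#'   zero charges and atom types equal to elements.
#' @export
read_res <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")

  cell <- NULL; latt <- 1L; symm <- list(); sfac <- character()
  atoms <- list()
  in_atoms <- FALSE
  for (i in seq_along(toks)) {
    t1 <- toupper(toks[[i]][1])
    if (t1 == "CELL") {
      v <- as.numeric(toks[[i]][-1])
      if (length(v) < 7 || anyNA(v[2:7]))
        stop("parse error: malformed CELL record", call. = FALSE)
      cell <- v[2:7]
    } else if (t1 == "LATT") {
      latt <- as.integer(toks[[i]][2])
    } else if (t1 == "SYMM") {
      symm[[length(symm) + 1]] <-
        parse_symm(paste(toks[[i]][-1], collapse = " "))
    } else if (t1 == "SFAC") {
      sfac <- toks[[i]][-1]
    } else if (t1 %in% c("ZERR", "UNIT", "TITL", "REM", "MORE", "FVAR",
                         "L.S.", "PLAN", "BOND", "LIST", "WGHT", "ACTA",
                         "TEMP", "SIZE")) {
      next
    } else if (t1 %in% c("END", "HKLF")) {
      break
    } else if (grepl("^[A-Za-z]", toks[[i]][1]) && length(toks[[i]]) >= 5) {
      v <- suppressWarnings(as.numeric(toks[[i]][2:5]))
      if (anyNA(v)) next
      if (any(abs(v[2:4]) > 5))
        stop("unsupported dialect: coordinates do not look fractional",
             call. = FALSE)
      atoms[[length(atoms) + 1]] <-
        list(label = toks[[i]][1], sfac = as.integer(v[1]), frac = v[2:4])
    }
  }
  if (is.null(cell)) stop("parse error: missing CELL record", call. = FALSE)
  if (length(atoms) == 0)
    stop("parse error: no atom records found", call. = FALSE)

  ops <- expand_latt_ops(latt, symm)
  lat <- lattice(cell[1], cell[2], cell[3], cell[4], cell[5], cell[6],
                 system = guess_system(cell))
  M <- cell_matrix(lat)
  mols <- lapply(atoms, function(a) {
    el <- if (length(sfac) >= a$sfac && a$sfac >= 1) sfac[a$sfac]
          else gsub("[0-9].*$", "", a$label)
    rigid_molecule(el, el, matrix(0, 1, 3), 0, center = a$frac)
  })
  cr <- crystal(lat, ops, mols, label = sub("\\.res$", "", basename(path)),
                check = FALSE)
  attr(cr, "atom_labels") <- vapply(atoms, function(a) a$label, "")
  cr
}

# LATT codes: |code| 1=P, 2=I, 3=R(obverse), 4=F, 5=A, 6=B, 7=C;
# positive code adds a center of inversion at the origin.
expand_latt_ops <- function(latt, symm) {
  cents <- switch(abs(latt),
    list(c(0, 0, 0)),
    list(c(0, 0, 0), c(0.5, 0.5, 0.5)),
    list(c(0, 0, 0), c(2/3, 1/3, 1/3), c(1/3, 2/3, 2/3)),
    list(c(0, 0, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0)),
    list(c(0, 0, 0), c(0, 0.5, 0.5)),
    list(c(0, 0, 0), c(0.5, 0, 0.5)),
    list(c(0, 0, 0), c(0.5, 0.5, 0)))
  if (is.null(cents)) stop("unknown LATT code: ", latt, call. = FALSE)
  base <- c(list(symop_identity()), symm)
  ops <- list()
  for (cn in cents) {
    for (op in base) {
      ops[[length(ops) + 1]] <- symop(op$R, op$t + cn)
      if (latt > 0)
        ops[[length(ops) + 1]] <- symop(-op$R, -op$t + cn)
    }
  }
  # deduplicate (rotation + translation mod 1)
  keys <- vapply(ops, function(o)
    paste(c(o$R, round(o$t %% 1, 6)), collapse = ","), "")
  ops <- ops[!duplicated(keys)]
  # identity first
  idx <- which(vapply(ops, is_identity_op, TRUE))
  c(ops[idx], ops[-idx])
}

guess_system <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4]; be <- cell[5]; ga <- cell[6]
  eq <- function(x, y) abs(x - y) < 1e-6
  if (eq(al, 90) && eq(be, 90) && eq(ga, 90)) {
    if (eq(a, b) && eq(b, cc)) return("cubic")
    if (eq(a, b)) return("tetragonal")
    return("orthorhombic")
  }
  if (eq(al, 90) && eq(ga, 90) && eq(a, b) && eq(ga, 90) && eq(be, 90))
    return("orthorhombic")
  if (eq(al, 90) && eq(be, 90) && eq(ga, 120) && eq(a, b))
    return("hexagonal")
  if (eq(al, 90) && eq(ga, 90)) return("monoclinic")
  "triclinic"
}

#' Write a crystal to a SHELX .res file
#'
#' Writes CELL, LATT/SYMM (LATT -1 with explicit SYMM records for every
#' non-identity operator), SFAC and fractional atom records. A read
#' back of the written file reproduces the cell to 1e-6 and the
#' fractional coordinates to 1e-6.
#'
#' @param cr An `xtl_crystal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_res <- function(cr, path) {
  st <- crystal_sites(cr, expand = FALSE, wrap = FALSE)
  elements <- unique(st$element)
  lines <- c(
    sprintf("TITL %s", cr$label),
    sprintf("CELL 1.0 %.6f %.6f %.6f %.6f %.6f %.6f",
            cr$lattice$a, cr$lattice$b, cr$lattice$c,
            cr$lattice$alpha, cr$lattice$beta, cr$lattice$gamma),
    sprintf("ZERR 1 0 0 0 0 0 0"),
    "LATT -1")
  for (k in seq_along(cr$ops)) {
    if (k == 1) next
    lines <- c(lines, sprintf("SYMM %s", symop_to_string(cr$ops[[k]])))
  }
  lines <- c(lines, paste("SFAC", paste(elements, collapse = " ")))
  n_el <- integer(length(elements))
  at_lines <- character(nrow(st$frac))
  for (i in seq_len(nrow(st$frac))) {
    ei <- match(st$element[i], elements)
    n_el[ei] <- n_el[ei] + 1L
    at_lines[i] <- sprintf("%s%d %d %.6f %.6f %.6f 1.0",
                           st$element[i], n_el[ei], ei,
                           st$frac[i, 1], st$frac[i, 2], st$frac[i, 3])
  }
  writeLines(c(lines, at_lines, "END"), path)
  invisible(path)
}

#' Read a training-set manifest
#'
#' The manifest is a YAML document binding `.res` geometry files to the
#' per-atom charges, atom-type labels, rigid-molecule partition,
#' reference intermolecular energy and merit-function weights of each
#' training structure:
#'
#' ```yaml
#' entries:
#'   - label: xtl001
#'     res: xtl001.res
#'     charges: [-0.5, 0.25, 0.25]
#'     types: [X, Y, Y]
#'     molecules: [[1, 2, 3]]
#'     u_inter_ref: -54.2
#'     w_g: 1        # optional, default 1
#'     w_e: 1        # optional; default 0 if any type is Hp, else 1
#' ```
#'
#' Paths are resolved relative to the manifest location. Entries are
#' returned in file order.
#'
#' @param path Manifest path.
#' @return List of [reference_entry()] objects, each carrying a fully
#'   assembled `xtl_crystal` (charges, types, rigid molecules).
#' @export
read_manifest <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$entries)) stop("manifest has no 'entries'", call. = FALSE)
  base <- dirname(normalizePath(path))
  lapply(doc$entries, function(e) {
    res_path <- if (file.exists(e$res)) e$res else file.path(base, e$res)
    raw <- read_res(res_path)
    manifest_entry_to_reference(e, raw)
  })
}

manifest_entry_to_reference <- function(e, raw) {
  st <- crystal_sites(raw, expand = FALSE, wrap = FALSE)
  nat <- nrow(st$frac)
  charges <- as.numeric(e$charges)
  types <- as.character(e$types)
  if (length(charges) != nat || length(types) != nat)
    stop("manifest entry '", e$label, "': charge/type count (",
         length(charges), ") does not match the .res atom count (", nat,
         ")", call. = FALSE)
  parts <- e$molecules
  if (is.null(parts)) parts <- list(seq_len(nat))
  used <- sort(unlist(parts))
  if (!identical(as.integer(used), seq_len(nat)))
    stop("manifest entry '", e$label,
         "': molecule partition must cover every atom exactly once",
         call. = FALSE)
  qtot <- sum(charges) * length(raw$ops)
  if (abs(qtot) > 1e-8)
    stop("manifest entry '", e$label, "': unit cell not neutral (net ",
         format(qtot), " e)", call. = FALSE)
  M <- cell_matrix(raw$lattice)
  Minv <- solve(M)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  mols <- lapply(parts, function(ix) {
    ix <- as.integer(ix)
    f <- st$frac[ix, , drop = FALSE]
    # unwrap the molecule so the rigid body is contiguous: move each
    # atom to the periodic image nearest the first atom, judged by
    # Cartesian distance (robust in strongly sheared cells)
    if (nrow(f) > 1) {
      x1 <- as.numeric(M %*% f[1, ])
      for (k in 2:nrow(f)) {
        cand <- sweep(shifts, 2, f[k, ], "+")
        d2 <- rowSums((cand %*% t(M) -
                         matrix(x1, nrow(cand), 3, byrow = TRUE))^2)
        f[k, ] <- cand[which.min(d2), ]
      }
    }
    cart <- f %*% t(M)
    cen <- colMeans(cart)
    rigid_molecule(st$element[ix], types[ix],
                   sweep(cart, 2, cen), charges[ix],
                   center = as.numeric(Minv %*% cen))
  })
  cr <- crystal(raw$lattice, raw$ops, mols,
                label = if (!is.null(e$label)) e$label else raw$label)
  w_g <- if (!is.null(e$w_g)) e$w_g else 1
  w_e <- e$w_e   # NULL applies the Hp default in reference_entry()
  reference_entry(cr, u_ref = e$u_inter_ref, w_g = w_g, w_e = w_e,
                  label = cr$label)
}

#' Write a training-set manifest (with .res files)
#'
#' Writes each entry's crystal as a `.res` file next to the manifest
#' and a YAML manifest referencing them; the inverse of
#' [read_manifest()].
#'
#' @param entries List of [reference_entry()].
#' @param dir Output directory (created if missing).
#' @param name Manifest file name.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(entries, dir, name = "manifest.yaml") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  docs <- lapply(entries, function(e) {
    cr <- e$crystal
    res_name <- paste0(cr$label, ".res")
    write_res(cr, file.path(dir, res_name))
    st <- crystal_sites(cr, expand = FALSE, wrap = FALSE)
    nat_per <- vapply(cr$molecules, n_atoms, 0L)
    stops <- cumsum(nat_per)
    startsv <- c(1L, head(stops, -1) + 1L)
    list(label = cr$label, res = res_name,
         charges = as.numeric(st$charge),
         types = as.character(st$type),
         molecules = lapply(seq_along(nat_per), function(m)
           seq(startsv[m], stops[m])),
         u_inter_ref = e$u_ref, w_g = e$w_g, w_e = e$w_e)
  })
  out <- file.path(dir, name)
  yaml::write_yaml(list(entries = docs), out, precision = 12)
  invisible(out)
}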