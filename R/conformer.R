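#' Atom-table conformers and ensembles
#'
#' A *conformer* is a tibble of atoms with columns `element`, `mass` (Da),
#' `resid` (author residue numbering), `chain`, `x`, `y`, `z` (Angstrom) and
#' optionally `atom` (atom name, e.g. "CA") and `resname`. An *ensemble* is
#' the same table with an additional integer `frame` column; every frame must
#' share one topology (identical atom count and ordering).
#'
#' @param atoms a data frame with at least `element`, `resid`, `x`, `y`, `z`.
#'   A `mass` column is filled in from [element_mass()] when absent; `chain`
#'   defaults to `"A"`.
#' @return a validated atom tibble.
#' @export
as_conformer <- function(atoms) {
  atoms <- as_tibble(atoms)
  required <- c("element", "resid", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("conformer table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  if (!"atom" %in% names(atoms)) atoms$atom <- "CA"
  if (!"mass" %in% names(atoms)) atoms$mass <- element_mass(atoms$element)
  if (nrow(atoms) == 0) abort("conformer has no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("conformer has non-finite coordinates")
  if (any(atoms$mass <= 0)) abort("atom masses must be positive")
  if (!all(vapply(split(atoms$resid, atoms$chain), Negate(is.unsorted), logical(1)))) {
    abort("residue indices must be non-decreasing within a chain")
  }
  atoms
}

#' @rdname as_conformer
#' @param frames a list of conformer tables, or a single table already
#'   carrying a `frame` column.
#' @export
as_ensemble <- function(frames) {
  if (is.data.frame(frames)) {
    if (!"frame" %in% names(frames)) frames$frame <- 1L
    ens <- as_tibble(frames)
  } else {
    if (length(frames) == 0) abort("ensemble is empty")
    ens <- bind_rows(lapply(seq_along(frames), function(i) {
      fr <- as_conformer(frames[[i]])
      fr$frame <- i
      fr
    }))
  }
  counts <- table(ens$frame)
  if (length(unique(counts)) != 1) {
    abort("all frames of an ensemble must have the same atom count")
  }
  ens
}

#' Split an ensemble into a list of conformer tables
#' @param ens an ensemble tibble (with a `frame` column).
#' @return named list of conformer tibbles, in frame order.
#' @export
ensemble_frames <- function(ens) {
  if (!"frame" %in% names(ens)) return(list(`1` = ens))
  split(dplyr::select(ens, -"frame"), ens$frame)
}

#' Number of frames in an ensemble
#' @param ens an ensemble tibble.
#' @export
n_frames <- function(ens) {
  if (!"frame" %in% names(ens)) return(1L)
  length(unique(ens$frame))
}

#' Read conformers from a coordinate file
#'
#' Reads single- or multi-model PDB files (via \pkg{bio3d}) or multi-frame
#' XYZ files into an ensemble tibble, one conformer per model/frame. Atom
#' ordering follows the file; heteroatoms such as structural Zn are kept as
#' ordinary heavy atoms.
#'
#' @param path file path.
#' @param format `"pdb"` (single- and multi-model) or `"xyz"`. Guessed from
#'   the file extension by default.
#' @return an ensemble tibble.
#' @export
read_coordinates <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (format == "pdb") read_pdb_models(path) else read_xyz(path)
}

read_pdb_models <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0) abort(paste0("no atoms in PDB file: ", path))
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- substr(trimws(at$elety[bad]), 1, 1)
  base <- tibble(
    element = toupper(elem),
    atom = trimws(at$elety),
    resname = at$resid,
    resid = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    mass = element_mass(toupper(elem))
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  if (n_models == 0) abort(paste0("no models in PDB file: ", path))
  bind_rows(lapply(seq_len(n_models), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    fr <- base
    fr$x <- co[, 1]; fr$y <- co[, 2]; fr$z <- co[, 3]
    fr$frame <- m
    fr
  }))
}

read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) == 0) abort(paste0("empty XYZ file: ", path))
  frames <- list()
  i <- 1L
  frame <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0) {
      abort(paste0("malformed XYZ atom count at line ", i, " of ", path))
    }
    if (i + 1L + nat > length(lines)) {
      abort(paste0("truncated XYZ frame starting at line ", i, " of ", path))
    }
    rec <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(rec), "\\s+")
    ok <- vapply(parts, length, integer(1)) >= 4
    if (!all(ok)) {
      abort(paste0("malformed XYZ atom record at line ", i + 1L + which(!ok)[1], " of ", path))
    }
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(co)) abort(paste0("non-numeric coordinates in XYZ frame at line ", i, " of ", path))
    el <- vapply(parts, `[[`, character(1), 1)
    frames[[frame]] <- tibble(
      element = toupper(el), atom = "X", resname = "UNK",
      resid = seq_len(nat), chain = "A",
      mass = element_mass(el),
      x = co[, 1], y = co[, 2], z = co[, 3], frame = frame
    )
    i <- i + 2L + nat
    frame <- frame + 1L
  }
  bind_rows(frames)
}

#' Write an ensemble to a (multi-model) PDB file
#'
#' @param ens ensemble or conformer tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(ens, path) {
  frames <- ensemble_frames(ens)
  multi <- length(frames) > 1
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(fr)) %% 100000,
      substr(fr$atom, 1, 4), substr(fr$resname, 1, 3),
      substr(fr$chain, 1, 1), fr$resid %% 10000,
      fr$x, fr$y, fr$z, 1.0, 0.0, substr(fr$element, 1, 2)
    )
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Domain definitions
#'
#' A domain definition is a tibble with columns `name`, `start`, `end`
#' (inclusive residue range in author numbering) and optionally `chain`.
#' [hoip_domains()] returns the RBR module layout of the HOIP E3 ligase
#' (author numbering 699-1071): the three zinc-binding subdomains used for
#' center-of-mass collective variables are RING1 699-751, IBR 796-841 and
#' RING2 869-934; the linkers L1/L2 and the C-terminal LDD complete the
#' construct.
#'
#' @param name,start,end domain name and inclusive residue range.
#' @param chain optional chain restriction.
#' @export
domain_def <- function(name, start, end, chain = NA_character_) {
  if (any(start > end)) abort("domain start must not exceed end")
  tibble(name = name, start = as.integer(start), end = as.integer(end), chain = chain)
}

#' @rdname domain_def
#' @export
hoip_domains <- function() {
  domain_def(
    name = c("RING1", "L1", "IBR", "L2", "RING2", "LDD"),
    start = c(699L, 752L, 796L, 842L, 869L, 935L),
    end = c(751L, 795L, 841L, 868L, 934L, 1071L)
  )
}

#' @rdname domain_def
#' @param path YAML file with a `domains:` list of `{name, start, end, chain}`
#'   entries (or a bare list of such entries).
#' @export
read_domains_yaml <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$domains)) y <- y$domains
  if (length(y) == 0) abort("no domain entries in YAML")
  bind_rows(lapply(y, function(d) {
    if (is.null(d$name) || is.null(d$start) || is.null(d$end)) {
      abort("each domain entry needs name, start and end")
    }
    domain_def(d$name, d$start, d$end, d$chain %||% NA_character_)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Logical atom selector for a residue range (single-row domain tibble or
# start/end pair); optionally restricted to one chain.
select_range <- function(conf, range) {
  if (is.data.frame(range)) {
    sel <- conf$resid >= range$start[1] & conf$resid <= range$end[1]
    if (!is.null(range$chain) && !is.na(range$chain[1])) {
      sel <- sel & conf$chain == range$chain[1]
    }
  } else {
    sel <- conf$resid >= range[1] & conf$resid <= range[2]
  }
  sel
}
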