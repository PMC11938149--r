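# Structure I/O, atom selection, superposition, renumbering.
#
# A structure is held as an atom table (topology) plus one coordinate
# matrix per conformer (MODEL in a multi-model PDB).  All conformers
# share atom count and order; coordinates are in Angstrom.

#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Parses a coordinate file into a `structure3d` object.  MODEL/ENDMDL
#' blocks (or `pdbx_PDB_model_num` in mmCIF) become conformers sharing
#' one topology.  Hydrogens are retained.  When alternate locations are
#' present, the highest-occupancy altloc is kept per atom and the number
#' of dropped records is logged.
#'
#' @param path Path to the file.
#' @param format `"pdb"` or `"mmcif"`; `"auto"` guesses from the file
#'   extension (`.cif`/`.mmcif` vs anything else).
#' @param keep_hetero Keep HETATM records (waters/ligands). Default `TRUE`;
#'   downstream interface and SASA calculations exclude them by default.
#' @return An object of class `structure3d`: a list with `atoms` (data
#'   frame: `serial`, `name`, `element`, `chain`, `resno`, `ins`,
#'   `resname`, `hydrogen`, `het`, `occ`), `xyz` (list of n x 3
#'   coordinate matrices, one per conformer) and `offsets` (named
#'   integer, renumbering applied per chain).
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' synth <- make_complex(n_res_a = 6, n_res_b = 6, n_contacts = 2, seed = 1)
#' write_structure(synth$structure, pdb)
#' s <- read_structure(pdb)
#' n_conformers(s)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_hetero = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) nd_stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  s <- switch(format, pdb = read_pdb_file(path), mmcif = read_mmcif_file(path))
  if (!keep_hetero) {
    keep <- !s$atoms$het
    s$atoms <- s$atoms[keep, , drop = FALSE]
    s$xyz <- lapply(s$xyz, function(m) m[keep, , drop = FALSE])
    rownames(s$atoms) <- NULL
  }
  s
}

new_structure3d <- function(atoms, xyz, offsets = integer(0)) {
  stopifnot(is.data.frame(atoms), is.list(xyz), length(xyz) >= 1L)
  for (m in xyz) stopifnot(is.matrix(m), ncol(m) == 3L, nrow(m) == nrow(atoms))
  if (anyNA(unlist(xyz)) || any(!is.finite(unlist(xyz))))
    nd_stop("non-finite coordinates")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz, offsets = offsets),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d atoms, %d conformer(s), chains: %s\n",
              nrow(x$atoms), length(x$xyz),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

#' Number of conformers in a structure
#' @param s A `structure3d`.
#' @return Integer count of conformers (models).
#' @export
n_conformers <- function(s) length(s$xyz)

guess_element <- function(name) {
  # PDB columns 13-16: element is right-justified in 13-14 for standard
  # names; fall back to first alphabetic character.
  nm <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CA" , "NA", "CL", "BR"),
         two, toupper(substr(nm, 1, 1)))
}

read_pdb_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- rec == "MODEL "
  is_endmdl <- rec == "ENDMDL"
  if (!any(is_atom)) nd_stop("no ATOM/HETATM records in ", path)

  # assign model index per atom line
  model_id <- cumsum(is_model)
  model_id[model_id == 0L] <- 1L
  atom_idx <- which(is_atom)
  amodel <- model_id[atom_idx]
  al <- lines[atom_idx]

  num <- function(txt, what, lineno) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.finite(v))
    if (length(bad))
      nd_stop(sprintf("parse error in %s line %d: bad %s field '%s'",
                      path, lineno[bad[1]], what, trimws(txt[bad[1]])))
    v
  }
  df <- data.frame(
    serial  = suppressWarnings(as.integer(substr(al, 7, 11))),
    name    = trimws(substr(al, 13, 16)),
    altloc  = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain   = substr(al, 22, 22),
    resno   = suppressWarnings(as.integer(substr(al, 23, 26))),
    ins     = trimws(substr(al, 27, 27)),
    het     = substr(al, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  xyzm <- cbind(num(substr(al, 31, 38), "x", atom_idx),
                num(substr(al, 39, 46), "y", atom_idx),
                num(substr(al, 47, 54), "z", atom_idx))
  occ <- suppressWarnings(as.numeric(substr(al, 55, 60)))
  occ[!is.finite(occ)] <- 1
  elem <- trimws(substr(al, 77, 78))
  elem <- ifelse(elem == "", guess_element(df$name), toupper(elem))
  if (anyNA(df$resno))
    nd_stop(sprintf("parse error in %s line %d: bad residue number",
                    path, atom_idx[which(is.na(df$resno))[1]]))
  df$element <- elem
  df$occ <- occ
  df$hydrogen <- elem %in% c("H", "D")

  assemble_conformers(df, xyzm, amodel, path)
}

# Resolve altlocs (keep highest occupancy) and split models into
# conformers, enforcing identical topology across models.
assemble_conformers <- function(df, xyzm, amodel, path) {
  models <- sort(unique(amodel))
  key <- function(d) paste(d$chain, d$resno, d$ins, d$name, sep = "|")
  per <- lapply(models, function(m) {
    sel <- amodel == m
    d <- df[sel, , drop = FALSE]
    m3 <- xyzm[sel, , drop = FALSE]
    if (any(d$altloc != " " & d$altloc != "")) {
      k <- key(d)
      ord <- order(k, -d$occ)
      d <- d[ord, , drop = FALSE]; m3 <- m3[ord, , drop = FALSE]
      k <- k[ord]
      keep <- !duplicated(k)
      if (sum(!keep) > 0)
        nd_log("dropped ", sum(!keep), " alternate-location atom records")
      d <- d[keep, , drop = FALSE]; m3 <- m3[keep, , drop = FALSE]
      ord2 <- order(d$serial)
      d <- d[ord2, , drop = FALSE]; m3 <- m3[ord2, , drop = FALSE]
    }
    list(atoms = d, xyz = m3)
  })
  n0 <- nrow(per[[1]]$atoms)
  for (i in seq_along(per)) {
    if (nrow(per[[i]]$atoms) != n0)
      nd_stop(sprintf(
        "inconsistent atom count across models in %s: model %d has %d atoms, model %d has %d",
        path, models[1], n0, models[i], nrow(per[[i]]$atoms)))
  }
  atoms <- per[[1]]$atoms
  atoms$altloc <- NULL
  atoms <- atoms[, c("serial", "name", "element", "chain", "resno", "ins",
                     "resname", "hydrogen", "het", "occ")]
  new_structure3d(atoms, lapply(per, `[[`, "xyz"))
}

# Minimal mmCIF reader: first _atom_site loop only.
read_mmcif_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tagline <- grep("^_atom_site\\.", lines)
  if (!length(tagline)) nd_stop("no _atom_site loop in ", path)
  tags <- sub("^_atom_site\\.", "", trimws(lines[tagline]))
  body_start <- max(tagline) + 1L
  body <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_") || startsWith(ln, "data_")) break
    body <- c(body, ln)
  }
  if (!length(body)) nd_stop("empty _atom_site loop in ", path)
  toks <- strsplit(body, "[[:space:]]+")
  nf <- lengths(toks)
  bad <- which(nf != length(tags))
  if (length(bad))
    nd_stop(sprintf("parse error in %s line %d: expected %d fields, got %d",
                    path, body_start + bad[1] - 1L, length(tags), nf[bad[1]]))
  tab <- do.call(rbind, toks)
  colnames(tab) <- tags
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(tab[, nm])
    rep(NA_character_, nrow(tab))
  }
  undot <- function(x, default = "") ifelse(x %in% c(".", "?") | is.na(x), default, x)
  df <- data.frame(
    serial  = as.integer(undot(pick("id"), "0")),
    name    = undot(pick("auth_atom_id", "label_atom_id")),
    altloc  = undot(pick("label_alt_id"), " "),
    resname = undot(pick("auth_comp_id", "label_comp_id")),
    chain   = undot(pick("auth_asym_id", "label_asym_id")),
    resno   = as.integer(undot(pick("auth_seq_id", "label_seq_id"), "0")),
    ins     = undot(pick("pdbx_PDB_ins_code")),
    het     = undot(pick("group_PDB"), "ATOM") == "HETATM",
    stringsAsFactors = FALSE
  )
  xyzm <- cbind(as.numeric(undot(pick("Cartn_x"), "NA")),
                as.numeric(undot(pick("Cartn_y"), "NA")),
                as.numeric(undot(pick("Cartn_z"), "NA")))
  if (any(!is.finite(xyzm))) nd_stop("non-numeric coordinates in ", path)
  occ <- suppressWarnings(as.numeric(undot(pick("occupancy"), "1")))
  occ[!is.finite(occ)] <- 1
  df$occ <- occ
  elem <- toupper(undot(pick("type_symbol")))
  df$element <- ifelse(elem == "", guess_element(df$name), elem)
  df$hydrogen <- df$element %in% c("H", "D")
  amodel <- as.integer(undot(pick("pdbx_PDB_model_num"), "1"))
  assemble_conformers(df, xyzm, amodel, path)
}

#' Write a structure as (multi-model) PDB
#'
#' @param s A `structure3d`.
#' @param path Output path.
#' @param remark Optional character vector written as REMARK records
#'   (e.g. generator provenance).
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, remark = NULL) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(remark))
    writeLines(sprintf("REMARK 999 %s", remark), con)
  multi <- length(s$xyz) > 1L
  for (k in seq_along(s$xyz)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    m <- s$xyz[[k]]
    rec <- ifelse(a$het, "HETATM", "ATOM  ")
    # column-13 convention: 1-3 char names start at column 14
    nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
    writeLines(sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       rec, a$serial %% 100000L, nm, " ", a$resname, a$chain,
                       a$resno, ifelse(a$ins == "", " ", a$ins),
                       m[, 1], m[, 2], m[, 3], a$occ, 0,
                       substr(a$element, 1, 2)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Select atoms from a structure
#'
#' Selection expressions are clauses joined by `and`:
#' \describe{
#'   \item{`chain A` / `chain A,B`}{chain identifier(s)}
#'   \item{`resi 11-90,95`}{residue number ranges (current numbering)}
#'   \item{`name CA,CB`}{atom names}
#'   \item{`backbone`}{atoms N, CA, C, O}
#'   \item{`heavy` / `noh`}{non-hydrogen atoms}
#'   \item{`hydro`}{hydrogen atoms only}
#'   \item{`all`}{no-op}
#'   \item{`nohet`}{exclude HETATM records}
#' }
#' An absent chain yields an empty selection with a logged warning.
#'
#' @param s A `structure3d`.
#' @param expr Selection expression string.
#' @param conformer Conformer (model) index the selection refers to.
#' @return An `atom_set`: list of `structure`, `conformer`, `idx`.
#' @export
select_atoms <- function(s, expr = "all", conformer = 1L) {
  stopifnot(inherits(s, "structure3d"))
  if (conformer < 1L || conformer > length(s$xyz))
    nd_stop("conformer index out of range: ", conformer)
  a <- s$atoms
  mask <- rep(TRUE, nrow(a))
  clauses <- trimws(strsplit(expr, "\\band\\b")[[1]])
  for (cl in clauses) {
    if (cl == "") next
    if (cl == "all") next
    if (cl %in% c("heavy", "noh")) { mask <- mask & !a$hydrogen; next }
    if (cl == "hydro") { mask <- mask & a$hydrogen; next }
    if (cl == "backbone") { mask <- mask & a$name %in% BACKBONE_NAMES & !a$het; next }
    if (cl == "nohet") { mask <- mask & !a$het; next }
    m <- regmatches(cl, regexec("^(chain|resi|name)[[:space:]]+(.+)$", cl))[[1]]
    if (length(m) != 3L) nd_stop("malformed selection clause: '", cl, "'")
    val <- m[3]
    if (m[2] == "chain") {
      ids <- trimws(strsplit(val, ",")[[1]])
      missing <- setdiff(ids, unique(a$chain))
      if (length(missing))
        nd_warn("selection names absent chain(s): ", paste(missing, collapse = ","))
      mask <- mask & a$chain %in% ids
    } else if (m[2] == "resi") {
      mask <- mask & a$resno %in% parse_ranges(val)
    } else {
      mask <- mask & a$name %in% trimws(strsplit(val, ",")[[1]])
    }
  }
  structure(list(structure = s, conformer = as.integer(conformer),
                 idx = which(mask)),
            class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("<atom_set> %d atoms (conformer %d)\n", length(x$idx), x$conformer))
  invisible(x)
}

#' Coordinates of an atom set
#' @param aset An `atom_set` (or an n x 3 matrix, returned as-is).
#' @return n x 3 coordinate matrix in Angstrom.
#' @export
atom_coords <- function(aset) {
  if (is.matrix(aset)) return(aset)
  stopifnot(inherits(aset, "atom_set"))
  aset$structure$xyz[[aset$conformer]][aset$idx, , drop = FALSE]
}

kabsch_fit <- function(P, Q) {
  # optimal rotation R (right multiplication of row vectors) with
  # det + 1 and translation mapping P onto Q
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)           # t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$u, sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cq - as.vector(cp %*% R)
  fitted <- sweep(P %*% R, 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Fits `mobile` onto `reference` (pairing atoms by list order) with an
#' SVD-based rigid-body fit; reflections are excluded (det = +1).
#'
#' @param mobile,reference `atom_set`s or n x 3 matrices with equal atom
#'   counts.
#' @return A `superposition`: `rotation` (3 x 3, applied by
#'   right-multiplication of row vectors), `translation` (length-3, in
#'   Angstrom) and `rmsd` (Angstrom, over the paired atoms after
#'   transformation).
#' @export
superpose <- function(mobile, reference) {
  P <- atom_coords(mobile); Q <- atom_coords(reference)
  if (nrow(P) != nrow(Q))
    nd_stop("atom count mismatch: ", nrow(P), " vs ", nrow(Q))
  if (nrow(P) < 3L) nd_stop("need at least 3 atoms to superpose")
  Pc <- sweep(P, 2, colMeans(P))
  if (svd(Pc)$d[2] < 1e-8) nd_stop("atoms are collinear; superposition is degenerate")
  out <- kabsch_fit(P, Q)
  structure(out, class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param xyz n x 3 matrix.
#' @param sp A `superposition`.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, sp) {
  sweep(xyz %*% sp$rotation, 2, sp$translation, "+")
}

#' RMSD between two atom sets
#'
#' @param a,b `atom_set`s or n x 3 matrices, equal counts, paired by order.
#' @param fit If `TRUE`, superpose `a` onto `b` first; otherwise RMSD in
#'   the current frames.
#' @return RMSD in Angstrom.
#' @export
rmsd_between <- function(a, b, fit = FALSE) {
  P <- atom_coords(a); Q <- atom_coords(b)
  if (nrow(P) != nrow(Q))
    nd_stop("atom count mismatch: ", nrow(P), " vs ", nrow(Q))
  if (nrow(P) == 0L) nd_stop("empty atom sets")
  if (fit) return(superpose(P, Q)$rmsd)
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Shift residue numbering per chain
#'
#' Applies integer offsets to residue numbers chain by chain (e.g. to
#' map author numbering onto UniProt numbering).  Original numbers are
#' retained in `atoms$orig_resno` the first time a structure is
#' renumbered.
#'
#' @param s A `structure3d`.
#' @param offsets Named integer vector, `chain id -> offset`.
#' @return Renumbered `structure3d`.
#' @export
renumber <- function(s, offsets) {
  stopifnot(inherits(s, "structure3d"))
  if (is.null(names(offsets)) || any(names(offsets) == ""))
    nd_stop("offsets must be a named (chain) vector")
  if (any(offsets != round(offsets))) nd_stop("offsets must be integers")
  a <- s$atoms
  if (is.null(a$orig_resno)) a$orig_resno <- a$resno
  for (ch in names(offsets)) {
    sel <- a$chain == ch
    a$resno[sel] <- a$resno[sel] + as.integer(offsets[[ch]])
  }
  rk <- unique(paste(a$chain, a$resno, a$ins, sep = "|"))
  rk0 <- unique(paste(s$atoms$chain, s$atoms$resno, s$atoms$ins, sep = "|"))
  if (length(rk) != length(rk0))
    nd_stop("renumbering created a residue-identifier collision (insertion codes)")
  prev <- s$offsets
  for (ch in names(offsets))
    prev[ch] <- (if (ch %in% names(prev)) prev[[ch]] else 0L) + as.integer(offsets[[ch]])
  new_structure3d(a, s$xyz, offsets = prev)
}
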