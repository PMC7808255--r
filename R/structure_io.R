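# Structure and frame-set I/O.
#
# A structure is a classed list holding an atom table (one row per atom)
# plus an identifier and an optional frame time label in ns. PDB reading
# and writing are delegated to bio3d; on top of that sit the policies this
# pipeline needs: alternate-location resolution (highest occupancy wins,
# ties by file order), element normalization with a fallback from atom
# names, and line-numbered validation of coordinate fields.

.two_letter_elements <- c(
  "CU", "FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE", "NI", "CO", "CD",
  "HG", "CA", "K"
)

.normalize_element <- function(x) {
  x <- toupper(trimws(x))
  ifelse(nchar(x) > 1,
         paste0(substr(x, 1, 1), tolower(substr(x, 2, nchar(x)))),
         x)
}

# Infer an element symbol from a PDB atom name when the element column is
# blank. HETATM names are checked against known two-letter symbols first
# ("CU" is copper); ATOM names take the first alphabetic character ("CA"
# is an alpha carbon).
.element_from_name <- function(name, type) {
  name <- toupper(gsub("[^A-Za-z]", "", trimws(name)))
  el <- substr(name, 1, 1)
  two <- substr(name, 1, 2)
  het <- type == "HETATM" & two %in% .two_letter_elements
  el[het] <- two[het]
  .normalize_element(el)
}

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns `type`, `serial`, `name`, `alt`,
#'   `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `occ`, `element`.
#'   Missing `type`/`alt`/`insert`/`occ` columns are filled with defaults.
#' @param id identifier string.
#' @param time optional frame time label in ns.
#' @return object of class `tyr_structure`.
#' @export
new_structure <- function(atoms, id = "structure", time = NULL) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) < 1L) stop("structure must contain at least one atom")
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element))
    atoms$element <- .element_from_name(atoms$name, atoms$type)
  need <- c("type", "serial", "name", "alt", "resid", "chain", "resno",
            "insert", "x", "y", "z", "occ", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("atom coordinates must be finite")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms[, need], id = id, time = time),
            class = "tyr_structure")
}

#' Read a PDB-format structure
#'
#' Parses a PDB v3.3 fixed-column file (via [bio3d::read.pdb]) into a
#' `tyr_structure`. HETATM records (metals, waters) are retained. When a
#' position carries alternate locations, the conformer with the highest
#' occupancy is kept; ties are broken by file order. Coordinate fields are
#' validated first and a malformed field is reported with its line number.
#'
#' @param file path to a PDB file.
#' @param id identifier; defaults to the file name.
#' @param time optional frame time label in ns.
#' @return a `tyr_structure`.
#' @export
read_pdb <- function(file, id = NULL, time = NULL) {
  if (!file.exists(file)) stop("file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM or HETATM records in ", file)
  for (i in which(is_atom)) {
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(lines[i], fld[1], fld[2])))
      if (is.na(v))
        stop("malformed coordinate field at line ", i, " of ", file)
    }
  }
  # rm.alt = FALSE: alternate locations are resolved here (highest
  # occupancy, ties by file order), not dropped wholesale
  pdb <- suppressWarnings(bio3d::read.pdb(file, verbose = FALSE,
                                          rm.alt = FALSE))
  a <- pdb$atom
  atoms <- data.frame(
    type = a$type, serial = a$eleno, name = a$elety,
    alt = ifelse(is.na(a$alt), "", a$alt),
    resid = a$resid, chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno, insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    element = ifelse(is.na(a$elesy) | trimws(a$elesy) == "",
                     .element_from_name(a$elety, a$type),
                     .normalize_element(a$elesy)),
    stringsAsFactors = FALSE
  )
  atoms <- .resolve_altloc(atoms)
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(file))
  new_structure(atoms, id = id, time = time)
}

#' Parse PDB-format text
#'
#' Same contract as [read_pdb] but takes the PDB content as a character
#' vector of lines (or one string with embedded newlines).
#'
#' @param text character vector of PDB lines.
#' @inheritParams read_pdb
#' @return a `tyr_structure`.
#' @export
parse_pdb <- function(text, id = "structure", time = NULL) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(text, tmp)
  tryCatch(read_pdb(tmp, id = id, time = time),
           error = function(e) stop(gsub(tmp, "<text>", conditionMessage(e),
                                         fixed = TRUE), call. = FALSE))
}

# Highest occupancy wins within each (chain, resno, insert, name) position;
# ties keep the first record in file order.
.resolve_altloc <- function(atoms) {
  has_alt <- atoms$alt != ""
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt & duplicated(key) | has_alt & key %in% key[duplicated(key)]])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    best <- idx[which.max(atoms$occ[idx])] # which.max: first max wins ties
    keep[setdiff(idx, best)] <- FALSE
  }
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a structure to a PDB file
#'
#' Emits PDB v3.3 fixed-column records via [bio3d::write.pdb]
#' (coordinates at 0.001 Angstrom precision, so read/write round trips
#' preserve them exactly).
#'
#' @param structure a `tyr_structure`.
#' @param file destination path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(structure, file) {
  a <- structure$atoms
  bio3d::write.pdb(
    file = file,
    type = a$type, eleno = a$serial, elety = a$name,
    resid = a$resid, chain = a$chain, resno = a$resno,
    insert = ifelse(a$insert == "", NA, a$insert),
    alt = ifelse(a$alt == "", NA, a$alt),
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    o = a$occ, b = rep(0, nrow(a)),
    elesy = toupper(a$element)
  )
  invisible(file)
}

#' Select atoms by attribute filters or an expression
#'
#' Returns the subset of atoms matching every supplied filter, in the
#' original order. Filters are combined with AND; an empty selection is
#' allowed (but the result is no longer a valid structure and is returned
#' as a zero-row structure that most operations will reject).
#'
#' @param structure a `tyr_structure`.
#' @param chain,resno,resid,name,element optional vectors of admissible
#'   chain IDs, residue numbers, residue names, atom names, elements.
#' @param expr optional one-sided formula whose right-hand side is
#'   evaluated over the atom-table columns, e.g.
#'   `~ name %in% c("ND1", "NE2") & resid == "HIS"`.
#' @return a `tyr_structure` with the matching atoms (possibly zero).
#' @export
select_atoms <- function(structure, chain = NULL, resno = NULL,
                         resid = NULL, name = NULL, element = NULL,
                         expr = NULL) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resid)) keep <- keep & a$resid %in% toupper(resid)
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element))
    keep <- keep & a$element %in% .normalize_element(element)
  if (!is.null(expr)) {
    if (!inherits(expr, "formula") || length(expr) != 2L)
      stop("'expr' must be a one-sided formula")
    val <- tryCatch(eval(expr[[2]], envir = a, enclos = environment(expr)),
                    error = function(e)
                      stop("invalid selection expression: ",
                           conditionMessage(e), call. = FALSE))
    if (!is.logical(val) || length(val) != nrow(a))
      stop("selection expression must yield one logical per atom")
    keep <- keep & !is.na(val) & val
  }
  out <- structure
  out$atoms <- a[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

# Heavy, non-water atom subset used by the geometric computations.
.geometry_atoms <- function(structure, include_hydrogens = FALSE,
                            include_water = FALSE) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!include_hydrogens) keep <- keep & a$element != "H"
  if (!include_water) keep <- keep & !(a$resid %in% c("HOH", "WAT"))
  a[keep, , drop = FALSE]
}

#' Assemble an ordered frame set
#'
#' Binds structures (e.g. MD snapshots exported at 0 and 100 ns) into a
#' trajectory. All frames must share the same atom identity sequence
#' (serial, atom name, residue name and number) and the time labels must
#' be strictly increasing.
#'
#' @param frames list of `tyr_structure` objects.
#' @param times numeric time labels in ns, one per frame; defaults to the
#'   frames' own `time` fields.
#' @return object of class `tyr_trajectory`.
#' @export
as_trajectory <- function(frames, times = NULL) {
  stopifnot(length(frames) >= 1L)
  if (is.null(times)) {
    times <- vapply(frames, function(f)
      if (is.null(f$time)) NA_real_ else f$time, numeric(1))
  }
  if (length(times) != length(frames) || anyNA(times))
    stop("one numeric time label per frame is required")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("time labels must be strictly increasing")
  ident <- function(f) paste(f$atoms$serial, f$atoms$name,
                             f$atoms$resid, f$atoms$resno, sep = "\r")
  ref <- ident(frames[[1]])
  for (k in seq_along(frames)[-1]) {
    if (!identical(ident(frames[[k]]), ref))
      stop("frame ", k, " does not share the atom identity sequence of frame 1")
  }
  structure(list(frames = frames, times = times), class = "tyr_trajectory")
}

#' Write records as a TSV table
#'
#' Header row followed by one row per record; tab-separated, UTF-8,
#' '.' decimal point. Numeric columns are written at full precision
#' (15 significant digits) so written tables round trip through
#' [read_table].
#'
#' @param records data.frame (or coercible) of records with a shared schema.
#' @param file destination path or connection.
#' @return `file`, invisibly.
#' @export
write_table <- function(records, file) {
  df <- as.data.frame(records)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) trimws(formatC(x, digits = 15,
                                                        format = "g")))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(file)
}

#' Read a TSV table written by [write_table]
#'
#' @param file path to a tab-separated file with a header row.
#' @return data.frame.
#' @export
read_table <- function(file) {
  read.delim(file, sep = "\t", stringsAsFactors = FALSE)
}

#' @export
print.tyr_structure <- function(x, ...) {
  cat("<tyr_structure> ", x$id,
      if (!is.null(x$time)) sprintf(" (t = %g ns)", x$time), "\n", sep = "")
  a <- x$atoms
  cat("  ", nrow(a), " atoms, ",
      length(unique(paste(a$chain, a$resno))), " residues, chains: ",
      paste(sort(unique(a$chain)), collapse = " "), "\n", sep = "")
  cat("  elements: ",
      paste(sprintf("%s (%d)", names(table(a$element)), table(a$element)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.tyr_trajectory <- function(x, ...) {
  cat("<tyr_trajectory> ", length(x$frames), " frames at t = ",
      paste(x$times, collapse = ", "), " ns; ",
      nrow(x$frames[[1]]$atoms), " atoms per frame\n", sep = "")
  invisible(x)
}
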