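#' @useDynLib pocketeer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif setNames
#' @importFrom utils read.csv head tail
NULL

# ---------------------------------------------------------------------------
# Van der Waals radii (Bondi 1964, A. Bondi, J. Phys. Chem. 68:441), the
# standard heavy-atom set used throughout structural bioinformatics.  The
# same table ships as inst/extdata/vdw_bondi.csv for user override.
# Hydrogens carry radius 0 by policy: they are flagged and never contribute
# to grid occupancy, energies, or SASA.
.vdw_bondi <- c(
  H = 0.0, D = 0.0,
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  SE = 1.90, B = 1.92,
  NA_ = 2.27, K = 2.75, MG = 1.73, CA_ = 2.31, ZN = 1.39,
  FE = 2.00, MN = 2.00, CU = 1.40, NI = 1.63, CO = 2.00
)
# NA/CA clash with R reserved-ish names; resolved via .radius_lookup()

.radius_lookup <- function(elements, table = .vdw_bondi) {
  key <- toupper(elements)
  key[key == "NA"] <- "NA_"
  key[key == "CA"] <- "CA_"
  unname(table[key])
}

.water_resnames <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3", "SOL")

#' Load a van der Waals radius table
#'
#' Reads a two-column CSV (element, radius) such as the packaged Bondi set
#' at `system.file("extdata", "vdw_bondi.csv", package = "pocketeer")`.
#'
#' @param path CSV file with columns `element`, `radius`.
#' @return Named numeric vector of radii in Angstrom.
#' @export
read_radius_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "radius") %in% names(tab)))
  out <- setNames(tab$radius, toupper(tab$element))
  names(out)[names(out) == "NA"] <- "NA_"
  names(out)[names(out) == "CA"] <- "CA_"
  out
}

#' Construct a residue selector
#'
#' Identifies one residue by chain, residue number, and optional PDB
#' insertion code, exactly as numbered in the source file.
#'
#' @param chain_id Single-character chain identifier.
#' @param residue_number Integer residue number.
#' @param insertion_code Optional single-character insertion code
#'   (`""` for none).
#' @return Object of class `residue_selector`.
#' @export
#' @examples
#' selector("A", 12)
selector <- function(chain_id, residue_number, insertion_code = "") {
  stopifnot(is.character(chain_id), nchar(chain_id) == 1L)
  residue_number <- as.integer(residue_number)
  stopifnot(!is.na(residue_number))
  structure(
    list(chain_id = chain_id, residue_number = residue_number,
         insertion_code = insertion_code),
    class = "residue_selector"
  )
}

#' @export
format.residue_selector <- function(x, ...) {
  paste0(x$chain_id, ":", x$residue_number, x$insertion_code)
}

#' @export
print.residue_selector <- function(x, ...) {
  cat("<residue_selector>", format(x), "\n")
  invisible(x)
}

#' Parse a "CHAIN:RESNUM[ICODE]" selector string
#' @param text e.g. `"A:52"` or `"A:52A"`.
#' @return A `residue_selector`.
#' @export
parse_selector <- function(text) {
  m <- regmatches(text, regexec("^(.):(-?[0-9]+)([A-Za-z]?)$", text))[[1]]
  if (length(m) == 0L)
    stop("cannot parse selector '", text, "' (expected CHAIN:RESNUM[ICODE])")
  selector(m[2], as.integer(m[3]), m[4])
}

# Element inference from the 4-character PDB atom-name field when the
# element columns (77-78) are blank.  Standard convention: a one-letter
# element is right-justified into column 14, so a leading blank or digit in
# column 13 means the element is the single letter at column 14 (" CA " ->
# C-alpha -> C); otherwise the first two characters form a two-letter
# element ("FE  " -> Fe, "CA  " -> calcium).
.infer_element <- function(name4) {
  c1 <- substr(name4, 1L, 1L)
  c2 <- substr(name4, 2L, 2L)
  ifelse(c1 == " " | grepl("[0-9]", c1),
         toupper(c2),
         toupper(paste0(c1, sub(" ", "", c2))))
}

.new_structure <- function(atoms, model_id = 1L, source_label = "") {
  stopifnot(is.data.frame(atoms))
  structure(list(atoms = atoms, model_id = as.integer(model_id),
                 source_label = source_label),
            class = "pocket_structure")
}

#' @export
print.pocket_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<pocket_structure> %d atoms (%d heavy), %d residue(s), model %d\n",
              nrow(a), sum(!a$is_h),
              nrow(unique(a[, c("chain_id", "residue_number", "insertion_code")])),
              x$model_id))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure A `pocket_structure`.
#' @param heavy_only Count only non-hydrogen atoms.
#' @return Integer count.
#' @export
n_atoms <- function(structure, heavy_only = FALSE) {
  if (heavy_only) sum(!structure$atoms$is_h) else nrow(structure$atoms)
}

#' Heavy-atom coordinate matrix
#' @param structure A `pocket_structure`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(structure) {
  a <- structure$atoms
  as.matrix(a[!a$is_h, c("x", "y", "z")])
}

#' Read a PDB file or text
#'
#' Parses ATOM/HETATM/MODEL/ENDMDL records.  Waters are dropped; hydrogens
#' are kept but flagged (`is_h`); for alternate locations only the highest
#' occupancy conformer is retained (ties broken by alphabetical alt_loc).
#' Coordinates are Angstrom and residue numbering follows the file verbatim.
#'
#' @param input Path to a PDB file, or a character vector of PDB lines, or a
#'   single string containing embedded newlines.
#' @param model_policy `"first"` (default) keeps only the first MODEL;
#'   `"all"` returns every model.
#' @return A list of `pocket_structure` objects (length 1 for
#'   `model_policy = "first"` or single-model files).
#' @export
read_pdb <- function(input, model_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  src <- "text"
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    src <- input
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (length(lines) == 0L) stop("empty PDB input")

  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- rec == "MODEL "
  if (!any(is_atom)) stop("no ATOM records in PDB input")

  # model id per line: cumulative MODEL count (0 -> single implicit model)
  model_of_line <- cumsum(is_model)
  if (max(model_of_line) == 0L) model_of_line <- model_of_line + 1L

  keep_models <- if (model_policy == "first") 1L else seq_len(max(model_of_line))
  out <- vector("list", length(keep_models))
  for (mi in seq_along(keep_models)) {
    m <- keep_models[mi]
    idx <- which(is_atom & model_of_line == m)
    if (length(idx) == 0L) stop("MODEL ", m, " contains no ATOM records")
    out[[mi]] <- .parse_atom_lines(lines[idx], idx, is_het = rec[idx] == "HETATM",
                                   model_id = m, source_label = src)
  }
  out
}

.parse_atom_lines <- function(al, line_numbers, is_het, model_id, source_label) {
  f <- function(a, b) substr(al, a, b)
  xs <- suppressWarnings(as.numeric(f(31, 38)))
  ys <- suppressWarnings(as.numeric(f(39, 46)))
  zs <- suppressWarnings(as.numeric(f(47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad) > 0L)
    stop("malformed coordinate field at line ", line_numbers[bad[1]],
         ": '", al[bad[1]], "'")
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1.0

  name4 <- f(13, 16)
  elem <- toupper(trimws(f(77, 78)))
  blank <- elem == ""
  if (any(blank)) elem[blank] <- .infer_element(name4[blank])

  atoms <- data.frame(
    serial = suppressWarnings(as.integer(f(7, 11))),
    name = trimws(name4),
    element = elem,
    residue_name = trimws(f(18, 20)),
    chain_id = f(22, 22),
    residue_number = suppressWarnings(as.integer(f(23, 26))),
    insertion_code = trimws(f(27, 27)),
    alt_loc = trimws(f(17, 17)),
    occupancy = pmin(pmax(occ, 0), 1),
    x = xs, y = ys, z = zs,
    is_het = is_het,
    stringsAsFactors = FALSE
  )
  atoms$is_h <- atoms$element %in% c("H", "D")
  atoms$vdw_radius <- NA_real_
  atoms$is_hydrophobic <- atoms$element %in% c("C", "S")

  # drop waters
  atoms <- atoms[!(atoms$is_het & atoms$residue_name %in% .water_resnames), ,
                 drop = FALSE]
  if (nrow(atoms) == 0L) stop("no non-water atoms in model ", model_id)

  # alt_loc policy: keep the highest-occupancy conformer per
  # (chain, residue, icode, name); ties -> alphabetically first alt_loc.
  # Deterministic by construction (stable order sort).
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code,
               atoms$name, sep = "\r")
  file_order <- seq_len(nrow(atoms))
  ord <- order(key, -atoms$occupancy, atoms$alt_loc)
  keep <- ord[!duplicated(key[ord])]
  atoms <- atoms[sort(file_order[keep]), , drop = FALSE]
  rownames(atoms) <- NULL

  if (!any(!atoms$is_h)) stop("structure has no heavy atoms")
  .new_structure(atoms, model_id = model_id, source_label = source_label)
}

#' Write structures to PDB format
#'
#' @param structures A `pocket_structure` or a list of them (written as
#'   MODEL/ENDMDL blocks when more than one).
#' @param path Output file; if `NULL` the lines are returned invisibly.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_pdb <- function(structures, path = NULL) {
  if (inherits(structures, "pocket_structure")) structures <- list(structures)
  multi <- length(structures) > 1L
  out <- character(0)
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    if (multi) out <- c(out, sprintf("MODEL     %4d", i))
    a <- s$atoms
    rec <- ifelse(a$is_het, "HETATM", "ATOM  ")
    name4 <- vapply(seq_len(nrow(a)), function(j) {
      nm <- a$name[j]
      # one-letter elements with short names are indented per PDB convention
      if (nchar(nm) <= 3L && nchar(a$element[j]) == 1L)
        formatC(paste0(" ", nm), width = -4L)
      else formatC(nm, width = -4L)
    }, character(1))
    out <- c(out, sprintf(
      "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, a$serial %% 100000L, name4, a$alt_loc, a$residue_name, a$chain_id,
      a$residue_number, a$insertion_code, a$x, a$y, a$z, a$occupancy, 0,
      formatC(a$element, width = 2L)))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Assign van der Waals radii by element
#'
#' @param structure A `pocket_structure`.
#' @param radius_set Either the name of the shipped table (`"bondi64"`) or a
#'   named numeric vector as returned by [read_radius_table()].
#' @return The structure with `vdw_radius` filled (0 for hydrogens).
#' @export
assign_radii <- function(structure, radius_set = "bondi64") {
  tab <- if (is.character(radius_set) && length(radius_set) == 1L) {
    if (radius_set != "bondi64")
      stop("unknown radius set '", radius_set, "'")
    .vdw_bondi
  } else radius_set
  a <- structure$atoms
  r <- .radius_lookup(a$element, tab)
  missing <- is.na(r) & !a$is_h
  if (any(missing)) {
    bad <- unique(a$element[missing])
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "), " (atoms ",
         paste(utils::head(a$serial[missing], 10L), collapse = ","), ")")
  }
  r[a$is_h] <- 0
  structure$atoms$vdw_radius <- r
  structure
}

#' Resolve a residue selector to its heavy atoms
#'
#' @param structure A `pocket_structure`.
#' @param sel A `residue_selector` (or "CHAIN:RESNUM" string).
#' @return Data frame of the residue's heavy atoms (subset of
#'   `structure$atoms` with a `row` column giving atom row indices).
#' @export
resolve_selector <- function(structure, sel) {
  if (is.character(sel)) sel <- parse_selector(sel)
  a <- structure$atoms
  hit <- a$chain_id == sel$chain_id &
    a$residue_number == sel$residue_number &
    a$insertion_code == sel$insertion_code &
    !a$is_h
  if (!any(hit))
    stop("residue ", format(sel), " not found (or has no heavy atoms)")
  out <- a[hit, , drop = FALSE]
  out$row <- which(hit)
  out
}

#' Remove hetero (non-polymer) atoms
#'
#' Pocket detection runs on the protein alone: any bound ligand must be
#' stripped before detecting the pocket it occupies.
#'
#' @param structure A `pocket_structure`.
#' @return Structure containing only ATOM-record atoms.
#' @export
strip_hetero <- function(structure) {
  a <- structure$atoms[!structure$atoms$is_het, , drop = FALSE]
  if (nrow(a) == 0L) stop("no polymer atoms left after stripping HETATM")
  rownames(a) <- NULL
  structure$atoms <- a
  structure
}

# residue table: one row per residue in file order, with atom row indices
.residue_table <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain_id, a$residue_number, a$insertion_code, sep = "\r")
  ord <- !duplicated(key)
  data.frame(chain_id = a$chain_id[ord],
             residue_number = a$residue_number[ord],
             insertion_code = a$insertion_code[ord],
             residue_name = a$residue_name[ord],
             key = key[ord],
             stringsAsFactors = FALSE)
}
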