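# Atomic coordinate input. PDB fixed-column records and a minimal mmCIF
# atom_site reader; atoms carry an element symbol and an atomic mass used
# as the density weight.

# Standard atomic masses (u) for elements common in macromolecular models.
ATOMIC_MASSES <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  "NA" = 22.990, MG = 24.305, P = 30.974, S = 32.06, CL = 35.45, K = 39.098,
  CA = 40.078, MN = 54.938, FE = 55.845, CO = 58.933, NI = 58.693,
  CU = 63.546, ZN = 65.38, SE = 78.971, BR = 79.904, I = 126.904,
  MO = 95.95, W = 183.84
)

element_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- ATOMIC_MASSES[el]
  miss <- is.na(m)
  if (any(miss)) {
    # fall back to the first character (e.g. "CA " atom name read as calcium
    # when the element column is absent is resolved by the caller; here an
    # unknown symbol degrades to its leading letter)
    first <- substr(el[miss], 1, 1)
    m2 <- ATOMIC_MASSES[first]
    bad <- unique(el[miss][!is.na(m2)])
    if (length(bad))
      warning("unknown element symbol(s) ", paste(bad, collapse = ", "),
              "; using mass of leading character")
    m[miss] <- m2
    if (anyNA(m)) {
      still <- unique(el[is.na(m)])
      warning("element(s) ", paste(still, collapse = ", "),
              " unrecognised; assigned carbon mass")
      m[is.na(m)] <- ATOMIC_MASSES[["C"]]
    }
  }
  unname(m)
}

#' Construct an atomic model
#'
#' @param element character vector of element symbols.
#' @param x,y,z coordinates in Angstrom.
#' @param weight per-atom weights; defaults to standard atomic masses.
#' @param chain,resid optional chain identifiers and residue numbers.
#' @return an object of class `atomic_model` (a data frame of atoms).
#' @export
atomic_model <- function(element, x, y, z, weight = NULL,
                         chain = NA_character_, resid = NA_integer_) {
  if (length(element) == 0L) stop("empty atomic model")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("non-finite coordinates")
  if (is.null(weight)) weight <- element_mass(element)
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weights must be positive and finite")
  df <- data.frame(element = as.character(element), weight = weight,
                   x = x, y = y, z = z,
                   chain = chain, resid = resid,
                   stringsAsFactors = FALSE)
  class(df) <- c("atomic_model", "data.frame")
  df
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model: %d atoms, %d chain(s), total weight %.1f u>\n",
              nrow(x), length(unique(x$chain)), sum(x$weight)))
  invisible(x)
}

is_atomic_model <- function(x) inherits(x, "atomic_model")

model_coords <- function(model) cbind(model$x, model$y, model$z)

model_com <- function(model) {
  w <- model$weight / sum(model$weight)
  c(sum(model$x * w), sum(model$y * w), sum(model$z * w))
}

#' Read atomic coordinates from a PDB or mmCIF file
#'
#' Parses `ATOM`/`HETATM` records. The element is taken from PDB columns
#' 77-78 when present, otherwise inferred from the atom name. Atomic masses
#' from a standard table serve as density weights.
#'
#' @param path file path (`.pdb` or `.cif`, auto-detected from content).
#' @param chain optional chain identifier(s) to keep.
#' @param residue_range optional `c(first, last)` residue-number range.
#' @param hetatm keep HETATM records (default TRUE).
#' @param drop_hydrogens drop H/D atoms (default TRUE).
#' @return an [atomic_model()].
#' @export
read_structure <- function(path, chain = NULL, residue_range = NULL,
                           hetatm = TRUE, drop_hydrogens = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  m <- if (any(startsWith(lines, "_atom_site."))) parse_cif_atoms(lines)
       else parse_pdb_atoms(lines)
  if (!hetatm) m <- m[m$record == "ATOM", , drop = FALSE]
  if (!is.null(chain)) m <- m[m$chain %in% chain, , drop = FALSE]
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    m <- m[!is.na(m$resid) & m$resid >= residue_range[1] &
             m$resid <= residue_range[2], , drop = FALSE]
  }
  if (drop_hydrogens) m <- m[!toupper(m$element) %in% c("H", "D"), , drop = FALSE]
  if (nrow(m) == 0L) stop("selection is empty (chain/residue filter too strict?)")
  atomic_model(m$element, m$x, m$y, m$z, chain = m$chain, resid = m$resid)
}

parse_pdb_atoms <- function(lines) {
  sel <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  lines <- lines[sel]
  if (!length(lines)) stop("no ATOM/HETATM records found")
  fld <- function(a, b) trimws(substr(lines, a, b))
  el <- fld(77, 78)
  name <- fld(13, 16)
  # infer element from atom name where the element column is blank
  blank <- el == ""
  el[blank] <- vapply(name[blank], function(nm) {
    s <- gsub("[^A-Za-z]", "", nm)
    if (nchar(s) >= 2 && toupper(substr(s, 1, 2)) %in% names(ATOMIC_MASSES) &&
        toupper(substr(s, 1, 2)) %in% c("FE", "ZN", "MG", "MN", "CU", "SE",
                                        "BR", "CL", "NA", "CA", "NI", "CO"))
      substr(s, 1, 2)
    else substr(s, 1, 1)
  }, character(1))
  data.frame(
    record = trimws(substr(lines, 1, 6)),
    element = el,
    chain = substr(lines, 22, 22),
    resid = suppressWarnings(as.integer(fld(23, 26))),
    x = as.numeric(fld(31, 38)),
    y = as.numeric(fld(39, 46)),
    z = as.numeric(fld(47, 54)),
    stringsAsFactors = FALSE)
}

parse_cif_atoms <- function(lines) {
  # locate the atom_site loop and its column order
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx)) stop("no _atom_site loop in mmCIF file")
  cols <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1L
  body <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_")) break
    body <- c(body, ln)
  }
  if (!length(body)) stop("empty _atom_site loop")
  toks <- strsplit(body, "[[:space:]]+")
  get <- function(row, nm, alt = NULL) {
    j <- match(nm, cols)
    if (is.na(j) && !is.null(alt)) j <- match(alt, cols)
    if (is.na(j)) return(NA_character_)
    row[j]
  }
  df <- do.call(rbind, lapply(toks, function(tk) {
    data.frame(
      record = get(tk, "group_PDB"),
      element = get(tk, "type_symbol"),
      chain = get(tk, "auth_asym_id", "label_asym_id"),
      resid = suppressWarnings(as.integer(get(tk, "auth_seq_id", "label_seq_id"))),
      x = as.numeric(get(tk, "Cartn_x")),
      y = as.numeric(get(tk, "Cartn_y")),
      z = as.numeric(get(tk, "Cartn_z")),
      stringsAsFactors = FALSE)
  }))
  df[df$record %in% c("ATOM", "HETATM"), , drop = FALSE]
}

#' Write an atomic model as a minimal PDB file
#'
#' @param model an [atomic_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(is_atomic_model(model))
  ch <- ifelse(is.na(model$chain), "A", substr(model$chain, 1, 1))
  rs <- ifelse(is.na(model$resid), 1L, model$resid)
  el <- toupper(substr(model$element, 1, 2))
  name <- sprintf("%-4s", substr(model$element, 1, 2))
  rec <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(model)) %% 100000L, name, "UNK", ch, rs %% 10000L,
    model$x, model$y, model$z, 1, 0, trimws(el))
  writeLines(c(rec, "END"), path)
  invisible(path)
}
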