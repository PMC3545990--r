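## Coordinate-file input and validated atom selections.  Parsing and
## writing of the PDB format are delegated to bio3d; the module exposes
## a flat, validated atom table for the geometry operations.

#' Read a coordinate file into a structure model
#'
#' Reads a PDB (or mmCIF) file and returns a validated atom table.
#' Alternate locations are collapsed to a single conformer by the
#' highest-occupancy rule (ties broken in favour of altloc "A") so that
#' downstream geometry sees one position per atom.  Waters and other
#' heteroatoms are retained and flagged (`is_water`, `is_het`).
#'
#' @param path coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param label optional accession/title label (defaults to file name).
#' @return Object of class `structure_model`: data frame with columns
#'   `chain`, `resno`, `icode`, `resid`, `atom`, `alt`, `element`, `x`,
#'   `y`, `z`, `occupancy`, `b`, `is_het`, `is_water`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_structure: no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("read_structure: cannot parse '", path,
                             "': ", conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0)
    stop("read_structure: empty model in ", path)
  occ <- ifelse(is.na(a$o), 1, a$o)
  if (any(occ < 0 | occ > 1))
    stop("read_structure: occupancy outside [0, 1] in ", path)
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- guess_element(a$elety)
  elem <- ifelse(is.na(elem) | elem == "", guess_element(a$elety), elem)
  model <- data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    icode = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    atom = a$elety,
    alt = ifelse(is.na(a$alt), "", a$alt),
    element = toupper(trimws(elem)),
    x = a$x, y = a$y, z = a$z,
    occupancy = occ,
    b = ifelse(is.na(a$b), 0, a$b),
    is_het = a$type == "HETATM",
    stringsAsFactors = FALSE)
  model$is_water <- model$resid %in% c("HOH", "WAT", "DOD")
  if (any(!is.finite(model$x + model$y + model$z)))
    stop("read_structure: non-finite coordinates in ", path)
  model <- collapse_altloc(model)
  key <- with(model, paste(chain, resno, icode, atom, alt))
  if (anyDuplicated(key))
    stop("read_structure: duplicate atoms after altloc collapse in ", path)
  structure(model, label = label %||% basename(path),
            class = c("structure_model", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_element <- function(atom_names) {
  nm <- gsub("[0-9']", "", trimws(atom_names))
  ifelse(substr(nm, 1, 2) %in% c("FE", "ZN", "MG", "CA", "NA", "CL", "MN",
                                 "SE", "BR"),
         substr(nm, 1, 2), substr(nm, 1, 1))
}

## keep the highest-occupancy alternate location per atom; ties -> 'A'
collapse_altloc <- function(model) {
  key <- with(model, paste(chain, resno, icode, atom))
  if (!anyDuplicated(key)) return(model)
  keep <- unlist(lapply(split(seq_len(nrow(model)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    sub <- model[idx, ]
    best <- idx[sub$occupancy == max(sub$occupancy)]
    if (length(best) > 1) {
      a <- best[model$alt[best] %in% c("A", "")]
      best <- if (length(a)) a[1] else best[1]
    }
    best
  }), use.names = FALSE)
  model[sort(keep), , drop = FALSE]
}

#' Select atoms from a structure model
#'
#' Filters by any combination of chain, residue number (+ insertion
#' code), residue name and atom name; waters and heteroatoms are
#' dropped unless requested.  The result preserves file order and an
#' empty selection is an error naming the selector.
#'
#' @param model a `structure_model`.
#' @param chain,resno,icode,resid,atom optional filters (vectors allowed).
#' @param het,water include heteroatoms / waters (default `FALSE`).
#' @return A `structure_model` subset, in file order.
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL, icode = NULL,
                         resid = NULL, atom = NULL, het = FALSE,
                         water = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  keep <- rep(TRUE, nrow(model))
  if (!het)   keep <- keep & (!model$is_het | model$is_water)
  if (!water) keep <- keep & !model$is_water
  if (!is.null(chain)) keep <- keep & model$chain %in% chain
  if (!is.null(resno)) keep <- keep & model$resno %in% resno
  if (!is.null(icode)) keep <- keep & model$icode %in% icode
  if (!is.null(resid)) keep <- keep & model$resid %in% resid
  if (!is.null(atom))  keep <- keep & model$atom %in% atom
  out <- model[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    sel <- paste(c(
      if (!is.null(chain)) paste0("chain=", paste(chain, collapse = ",")),
      if (!is.null(resno)) paste0("resno=", paste(resno, collapse = ",")),
      if (!is.null(resid)) paste0("resid=", paste(resid, collapse = ",")),
      if (!is.null(atom)) paste0("atom=", paste(atom, collapse = ","))),
      collapse = " ")
    stop("empty selection: ", if (nzchar(sel)) sel else "<all>",
         " in ", attr(model, "label"))
  }
  attr(out, "label") <- attr(model, "label")
  class(out) <- class(model)
  out
}

#' Parse a `chain:resnum[:atom]` selector string
#'
#' @param s selector string, e.g. `"A:17"` or `"A:17:CA"`.
#' @return List with `chain`, `resno` and optionally `atom`, suitable
#'   for `do.call(select_atoms, c(list(model), sel))`.
#' @export
parse_selector <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2 || length(parts) > 3)
    stop("selector must be chain:resnum[:atom], got '", s, "'")
  sel <- list(chain = parts[1],
              resno = suppressWarnings(as.integer(parts[2])))
  if (is.na(sel$resno)) stop("selector residue number is not an integer: ", s)
  if (length(parts) == 3) sel$atom <- parts[3]
  sel
}

#' Coordinate matrix of a structure model (n x 3)
#'
#' @param model a `structure_model` (or any data frame with x/y/z).
#' @return Numeric matrix with columns x, y, z.
#' @export
coords <- function(model) {
  as.matrix(model[, c("x", "y", "z")])
}

#' Write a structure model as a PDB file
#'
#' @param model a `structure_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  bio3d::write.pdb(file = path,
                   type = ifelse(model$is_het, "HETATM", "ATOM"),
                   xyz = as.numeric(t(coords(model))),
                   resno = model$resno, resid = model$resid,
                   eleno = seq_len(nrow(model)), elety = model$atom,
                   chain = ifelse(model$chain == "", " ", model$chain),
                   insert = ifelse(model$icode == "", "", model$icode),
                   o = model$occupancy, b = model$b,
                   elesy = model$element)
  invisible(path)
}

#' Build a structure model from an atom table (for constructed fixtures)
#'
#' @param chain,resno,resid,atom,element,x,y,z vectors of equal length
#'   (recycled where scalar); remaining columns get defaults.
#' @param label model label.
#' @return A `structure_model`.
#' @export
structure_model <- function(chain, resno, resid, atom, element, x, y, z,
                            label = "constructed") {
  n <- max(lengths(list(chain, resno, resid, atom, element, x, y, z)))
  model <- data.frame(chain = rep_len(chain, n), resno = rep_len(resno, n),
                      icode = "", resid = rep_len(resid, n),
                      atom = rep_len(atom, n), alt = "",
                      element = toupper(rep_len(element, n)),
                      x = rep_len(x, n), y = rep_len(y, n),
                      z = rep_len(z, n),
                      occupancy = 1, b = 0, is_het = FALSE,
                      is_water = FALSE, stringsAsFactors = FALSE)
  structure(model, label = label,
            class = c("structure_model", "data.frame"))
}
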