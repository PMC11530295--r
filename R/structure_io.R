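# Reading protein structures and extracting a single chain's backbone.

.AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Construct a backbone structure object
#'
#' A `backbone` holds one protein chain's backbone: per-residue N, CA and
#' C coordinates (required), optional O and CB coordinates, one-letter
#' amino-acid codes and sequential residue positions.  Coordinates are in
#' Angstrom; positions are 1-based and strictly increasing.
#'
#' @param chain_id chain identifier (single string).
#' @param aa character vector of one-letter amino-acid codes (21-letter
#'   alphabet, `"X"` for non-standard residues).
#' @param N,CA,C numeric L x 3 coordinate matrices (required atoms).
#' @param O,CB optional L x 3 coordinate matrices; missing atoms are `NA`
#'   rows.
#' @param resno original author residue numbers (defaults to `1:L`).
#' @return an object of class `backbone`.
#' @export
new_backbone <- function(chain_id, aa, N, CA, C, O = NULL, CB = NULL,
                         resno = NULL) {
  L <- length(aa)
  as_m <- function(x) {
    if (is.null(x)) return(matrix(NA_real_, L, 3L))
    x <- as.matrix(x)
    stopifnot(nrow(x) == L, ncol(x) == 3L)
    x
  }
  N <- as_m(N); CA <- as_m(CA); C <- as_m(C); O <- as_m(O); CB <- as_m(CB)
  if (L > 0 && (anyNA(N) || anyNA(CA) || anyNA(C) ||
                !all(is.finite(N)) || !all(is.finite(CA)) ||
                !all(is.finite(C)))) {
    stop("every residue must have finite N, CA and C coordinates")
  }
  if (is.null(resno)) resno <- seq_len(L)
  stopifnot(!any(aa %in% .AA_ALPHABET == FALSE))
  structure(
    list(chain_id = as.character(chain_id), aa = aa,
         seq_pos = seq_len(L), resno = as.integer(resno),
         N = N, CA = CA, C = C, O = O, CB = CB),
    class = "backbone"
  )
}

#' @export
length.backbone <- function(x) length(x$aa)

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> chain %s, %d residues\n", x$chain_id, length(x)))
  cat(" sequence:", paste(x$aa, collapse = ""), "\n")
  invisible(x)
}

#' One-letter sequence of a backbone
#' @param s a `backbone`.
#' @return single string.
#' @export
backbone_sequence <- function(s) paste(s$aa, collapse = "")

#' Parse a protein structure file and extract one chain's backbone
#'
#' Reads a PDB (or mmCIF) file through [bio3d::read.pdb()] /
#' [bio3d::read.cif()], keeps the first model of multi-model entries,
#' resolves alternate locations to the highest-occupancy conformer (ties
#' to the first listed), and drops residues missing any of N, CA, C with
#' a warning.  Non-standard residues map to `"X"`; selenomethionine maps
#' to methionine.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param chain chain identifier, or `"first"` for the first chain seen.
#' @return a [new_backbone()] object.
#' @export
parse_structure <- function(path, chain = "first") {
  if (!file.exists(path)) stop("structure file not found: ", path)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- if (is_cif) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  }
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at <- at[at$resid %in% names(.AA3) | at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no parsable residues in ", path)

  if (identical(chain, "first")) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain not found: ", chain)

  # resolve altLoc: within (residue, atom name) keep highest occupancy,
  # ties to the first listed record
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -occ,
               seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(paste(at$resno, at$insert, sep = "\r"),
                       unique(paste(at$resno, at$insert, sep = "\r")))), ,
           drop = FALSE]

  rkey <- paste(at$resno, at$insert, sep = "\r")
  res_ids <- unique(rkey)
  get_atom <- function(rows, name) {
    hit <- rows[rows$elety == name, , drop = FALSE]
    if (nrow(hit) == 0) return(rep(NA_real_, 3L))
    c(hit$x[1L], hit$y[1L], hit$z[1L])
  }
  L0 <- length(res_ids)
  Nm <- CAm <- Cm <- Om <- CBm <- matrix(NA_real_, L0, 3L)
  aa <- character(L0); rn <- integer(L0)
  for (i in seq_len(L0)) {
    rows <- at[rkey == res_ids[i], , drop = FALSE]
    Nm[i, ] <- get_atom(rows, "N")
    CAm[i, ] <- get_atom(rows, "CA")
    Cm[i, ] <- get_atom(rows, "C")
    Om[i, ] <- get_atom(rows, "O")
    CBm[i, ] <- get_atom(rows, "CB")
    code <- .AA3[rows$resid[1L]]
    aa[i] <- if (is.na(code)) "X" else unname(code)
    rn[i] <- rows$resno[1L]
  }
  ok <- stats::complete.cases(Nm) & stats::complete.cases(CAm) &
    stats::complete.cases(Cm)
  if (!all(ok)) {
    warning(sprintf("dropped %d residue(s) missing N/CA/C in chain %s",
                    sum(!ok), chain))
  }
  if (!any(ok)) stop("no residue with complete N/CA/C backbone in chain ",
                     chain)
  new_backbone(chain, aa[ok], Nm[ok, , drop = FALSE], CAm[ok, , drop = FALSE],
               Cm[ok, , drop = FALSE], Om[ok, , drop = FALSE],
               CBm[ok, , drop = FALSE], resno = rn[ok])
}

#' Idealized C-beta position from backbone atoms
#'
#' Places a virtual C-beta from tetrahedral backbone geometry using the
#' fixed published coefficients on `b = CA - N`, `c = C - CA` and
#' `a = b x c`.  Used wherever a residue (glycine in particular) carries
#' no experimental C-beta.
#'
#' @param N,CA,C numeric length-3 coordinates (Angstrom).
#' @return length-3 C-beta coordinate.
#' @export
virtual_cbeta <- function(N, CA, C) {
  b <- CA - N
  cc <- C - CA
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  if (sqrt(sum(a * a)) < 1e-7) {
    stop("degenerate backbone geometry: N, CA, C are collinear")
  }
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + CA
}

# Apply a rigid motion (rotation R, translation t) to all coordinates.
transform_backbone <- function(s, R, t = c(0, 0, 0)) {
  tr <- function(m) {
    out <- m
    ok <- stats::complete.cases(m)
    if (any(ok)) out[ok, ] <- sweep(m[ok, , drop = FALSE] %*% t(R), 2L, -t, "-")
    out
  }
  s$N <- tr(s$N); s$CA <- tr(s$CA); s$C <- tr(s$C)
  s$O <- tr(s$O); s$CB <- tr(s$CB)
  s
}

#' Write a backbone to a PDB file
#'
#' Emits standard ATOM records for the stored backbone atoms (N, CA, C,
#' and O/CB where present).  An optional per-residue score is written
#' into the B-factor column.
#'
#' @param s a `backbone`.
#' @param path output file path.
#' @param bfactor optional numeric vector (length of `s`) for the
#'   B-factor column.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(s, path, bfactor = NULL) {
  if (is.null(bfactor)) bfactor <- rep(0, length(s))
  stopifnot(length(bfactor) == length(s))
  rev3 <- names(.AA3)[match(s$aa, .AA3)]
  rev3[is.na(rev3)] <- "UNK"
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (i in seq_len(length(s))) {
    for (nm in c("N", "CA", "C", "O", "CB")) {
      xyz <- s[[nm]][i, ]
      if (anyNA(xyz)) next
      serial <- serial + 1L
      el <- substr(nm, 1L, 1L)
      writeLines(sprintf(
        "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, " ", rev3[i], s$chain_id, s$resno[i],
        xyz[1], xyz[2], xyz[3], 1.00, bfactor[i], el), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
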