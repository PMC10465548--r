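#' Atomic masses and Lennard-Jones parameter table
#'
#' The bundled LJ table is AMBER ff99-style generic van der Waals
#' parameters keyed by element, stored as (Rmin/2, epsilon). Specific
#' (residue, atom-name) rows may be prepended by the caller; lookup tries
#' (residue, atom) first, then the element inferred from the atom name.
#' Unknown elements fail loudly rather than defaulting silently.
#'
#' @keywords internal
#' @name lj_table
NULL

.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  FE = 55.845, SE = 78.971
)

#' Default element-keyed LJ parameter table
#'
#' @return data.frame with columns `residue` ("*" for any), `atom` (element
#'   symbol for fallback rows), `epsilon` (kcal/mol), `rmin2` (Rmin/2, in
#'   Angstrom).
#' @export
default_lj_table <- function() {
  data.frame(
    residue = "*",
    atom = c("H", "C", "N", "O", "S", "P"),
    epsilon = c(0.0157, 0.0860, 0.1700, 0.2100, 0.2500, 0.2000),
    rmin2 = c(0.6000, 1.9080, 1.8240, 1.6612, 2.0000, 2.1000),
    stringsAsFactors = FALSE
  )
}

#' Infer an element symbol from a PDB/PQR atom name
#'
#' Leading digits are stripped; two-letter symbols are recognised for
#' halogens and common metals, otherwise the first letter is used.
#'
#' @param name atom-name string(s).
#' @return element symbol(s).
#' @export
infer_element <- function(name) {
  vapply(name, function(nm) {
    s <- toupper(gsub("^[0-9]+", "", trimws(nm)))
    if (nchar(s) == 0L) stop("cannot infer element from atom name '", nm, "'")
    two <- substr(s, 1, 2)
    if (two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "SE")) return(two)
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

lj_lookup <- function(residue_name, atom_name, lj_table, sigma_convention) {
  el <- infer_element(atom_name)
  n <- length(atom_name)
  eps <- numeric(n); rmin2 <- numeric(n)
  key_specific <- paste(lj_table$residue, lj_table$atom)
  for (k in seq_len(n)) {
    i <- match(paste(residue_name[k], atom_name[k]), key_specific)
    if (is.na(i)) i <- match(paste("*", el[k]), key_specific)
    if (is.na(i)) {
      stop("no LJ parameters for atom '", atom_name[k], "' (residue ",
           residue_name[k], ", element ", el[k], ")")
    }
    eps[k] <- lj_table$epsilon[i]
    rmin2[k] <- lj_table$rmin2[i]
  }
  sigma <- switch(sigma_convention,
    rmin  = 2 * rmin2,
    sigma = 2 * rmin2 / 2^(1 / 6),
    stop("sigma_convention must be 'rmin' or 'sigma'")
  )
  list(epsilon = eps, sigma = sigma)
}

#' Construct a rigid molecule
#'
#' The unit of all energetics: an ordered atom table with coordinates
#' (Angstrom), partial charges (e), and self-pair LJ parameters. Coordinates
#' are re-centred so the geometric centre is at the origin.
#'
#' @param atoms data.frame with columns `serial`, `name`, `residue_name`,
#'   `residue_index`, `chain`, `x`, `y`, `z`, `charge`, `lj_epsilon`,
#'   `lj_sigma`.
#' @param label molecule label.
#' @return object of class `rigid_molecule` with elements `label`, `atoms`
#'   (with added `core_radius = lj_sigma/2`), `center` (original geometric
#'   centre before recentring) and `residues` (ordered residue table).
#' @export
rigid_molecule <- function(atoms, label = "molecule") {
  need <- c("serial", "name", "residue_name", "residue_index", "chain",
            "x", "y", "z", "charge", "lj_epsilon", "lj_sigma")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (any(atoms$lj_epsilon < 0)) stop("lj_epsilon must be >= 0")
  if (any(atoms$lj_sigma <= 0)) stop("lj_sigma must be > 0")
  ctr <- c(mean(atoms$x), mean(atoms$y), mean(atoms$z))
  atoms$x <- atoms$x - ctr[1]
  atoms$y <- atoms$y - ctr[2]
  atoms$z <- atoms$z - ctr[3]
  atoms$core_radius <- atoms$lj_sigma / 2
  res <- unique(atoms[, c("residue_name", "residue_index")])
  res <- res[order(match(res$residue_index, atoms$residue_index)), ]
  rownames(res) <- NULL
  structure(list(label = label, atoms = atoms, center = ctr, residues = res),
            class = "rigid_molecule")
}

#' @export
print.rigid_molecule <- function(x, ...) {
  cat("<rigid_molecule>", x$label, ":", nrow(x$atoms), "atoms,",
      nrow(x$residues), "residues, net charge",
      sprintf("%.3f", sum(x$atoms$charge)), "e\n")
  invisible(x)
}

#' Centred atom coordinates of a molecule
#' @param mol a `rigid_molecule`.
#' @return n_atoms x 3 matrix, Angstrom.
#' @export
molecule_coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Radius of the smallest origin-centred sphere enclosing all hard cores
#' @param mol a `rigid_molecule`.
#' @return radius in Angstrom.
#' @export
molecule_radius <- function(mol) {
  xyz <- molecule_coords(mol)
  max(sqrt(rowSums(xyz^2)) + mol$atoms$core_radius)
}

#' Read a PQR file into a rigid molecule
#'
#' Whitespace-tolerant parser for PDB2PQR-style ATOM/HETATM records
#' (`... x y z charge radius`). Charges and file radii are taken verbatim;
#' LJ epsilon/sigma are assigned from `lj_table` (see
#' [default_lj_table()]).
#'
#' @param path PQR file path.
#' @param label molecule label (defaults to file name).
#' @param lj_table LJ parameter table; rows with `residue != "*"` override
#'   element fallbacks for matching (residue, atom-name) pairs.
#' @param sigma_convention `"rmin"` (hard-core radius = tabulated Rmin/2,
#'   default) or `"sigma"` (Rmin/2 converted to the LJ zero-crossing
#'   convention by 2^(1/6)).
#' @return a [rigid_molecule()].
#' @export
read_pqr <- function(path, label = NULL,
                     lj_table = default_lj_table(),
                     sigma_convention = c("rmin", "sigma")) {
  sigma_convention <- match.arg(sigma_convention)
  lines <- readLines(path)
  keep <- grepl("^(ATOM|HETATM)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no ATOM/HETATM records in ", path)
  recs <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    tok <- strsplit(trimws(lines[idx[j]]), "[[:space:]]+")[[1]]
    # record serial name resname [chain] resseq x y z q r
    if (length(tok) == 11L) {
      chain <- tok[5]; rest <- tok[6:11]
    } else if (length(tok) == 10L) {
      chain <- ""; rest <- tok[5:10]
    } else {
      stop("malformed PQR record at line ", idx[j], ": expected 10 or 11 fields, got ",
           length(tok))
    }
    num <- suppressWarnings(as.numeric(rest))
    if (anyNA(num) || anyNA(suppressWarnings(as.integer(c(tok[2], rest[1]))))) {
      stop("malformed PQR record at line ", idx[j], ": non-numeric field")
    }
    recs[[j]] <- data.frame(
      serial = as.integer(tok[2]), name = tok[3], residue_name = tok[4],
      residue_index = as.integer(rest[1]), chain = chain,
      x = num[2], y = num[3], z = num[4], charge = num[5], radius = num[6],
      stringsAsFactors = FALSE
    )
  }
  atoms <- do.call(rbind, recs)
  lj <- lj_lookup(atoms$residue_name, atoms$name, lj_table, sigma_convention)
  atoms$lj_epsilon <- lj$epsilon
  atoms$lj_sigma <- lj$sigma
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  rigid_molecule(atoms, label = label)
}

#' Write a rigid molecule as a PQR file
#'
#' Coordinates are written in the molecule's centred frame; the radius
#' column holds the hard-core radius (`lj_sigma/2`).
#'
#' @param mol a `rigid_molecule`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(mol, path) {
  a <- mol$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-4s %s%4d %11.4f %11.4f %11.4f %8.4f %7.4f",
    a$serial, a$name, a$residue_name,
    ifelse(nzchar(a$chain), a$chain, "A"), a$residue_index,
    a$x, a$y, a$z, a$charge, a$core_radius
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Molecular mass from standard atomic masses
#'
#' Elements are inferred from atom names; needed to convert copy numbers in
#' a periodic box into mg/ml concentrations.
#'
#' @param mol a `rigid_molecule`.
#' @return mass in Dalton.
#' @export
molecule_mass <- function(mol) {
  el <- infer_element(mol$atoms$name)
  m <- .atomic_masses[el]
  if (anyNA(m)) {
    stop("no atomic mass for element(s): ",
         paste(unique(el[is.na(m)]), collapse = ", "))
  }
  sum(m)
}

#' Read an aligned multi-FASTA file
#'
#' @param path FASTA file; all sequences must have equal (aligned) length.
#' @return data.frame with columns `id` and `seq` (1-letter residues,
#'   possibly containing '-' gaps), in file order.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (!length(ss)) stop("no sequences in ", path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L) {
    bad <- names(ss)[w != w[1]][1]
    stop("alignment lengths differ: sequence '", bad, "' has length ",
         w[w != w[1]][1], " vs ", w[1])
  }
  data.frame(id = names(ss), seq = as.character(ss),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percent sequence identity
#'
#' For equal-length inputs the sequences are treated as aligned; otherwise
#' a global Needleman-Wunsch alignment (BLOSUM62, gap open 10 / extend 0.5)
#' is performed first. Identity is counted over columns where both
#' sequences are non-gap.
#'
#' @param a,b sequences as character strings (gaps '-') or single rows of
#'   [read_alignment()] output.
#' @return identity percentage (numeric, not rounded).
#' @export
percent_identity <- function(a, b) {
  a <- if (is.list(a) || is.data.frame(a)) a$seq else a
  b <- if (is.list(b) || is.data.frame(b)) b$seq else b
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (nchar(a) != nchar(b)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5
    )
    a <- as.character(Biostrings::alignedPattern(aln))
    b <- as.character(Biostrings::alignedSubject(aln))
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) stop("no gap-free aligned columns")
  100 * sum(ca[both] == cb[both]) / sum(both)
}
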