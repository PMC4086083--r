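## Library preparation: counter-ion removal, rule-based pH 7.4 ionization
## and annotation. Every molecule entering an index passes through
## standardize_smiles() exactly once, at library-build time.

#' Remove counter ions from a SMILES string
#'
#' Keeps the fragment with the most heavy atoms; ties are broken by more
#' carbons, then by the lexicographically smallest canonical fragment
#' string. The retained fragment is returned in canonical form.
#'
#' @param raw_smiles character vector of (possibly multi-fragment) SMILES.
#' @return character vector of single-fragment canonical SMILES.
#' @export
strip_counter_ions <- function(raw_smiles) {
  can <- canonical_smiles(raw_smiles)
  if (anyNA(can)) {
    bad <- which(is.na(can))
    stop("unparseable SMILES at position ", bad[1L], ": ",
         raw_smiles[bad[1L]])
  }
  vapply(can, function(s) {
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(frags) == 1L) return(s)
    frags <- canonical_smiles(frags)
    cnt <- vapply(frags, fragment_atom_counts, numeric(2))
    ord <- order(-cnt["heavy", ], -cnt["carbon", ], frags)
    frags[ord[1L]]
  }, character(1), USE.NAMES = FALSE)
}

## --- pH 7.4 rule table -----------------------------------------------------
## Deprotonate: carboxylic, sulfonic, phosphonic/phosphoric acid O-H.
## Protonate:   aliphatic primary/secondary/tertiary amines; the imine-type
##              nitrogen of amidines and guanidines.
## Neutral:     anilines, amides, alcohols, phenols (no rule matches them).
## Operates on the kekulized graph and returns modified formal charges,
## or NULL when no rule fires.
.ph74_charges <- function(g) {
  n <- length(g$elem)
  if (n == 0L || nrow(g$bonds) == 0L) return(NULL)
  deg <- .graph_degree(g)
  charge <- g$charge
  bonds <- g$bonds

  nbrs <- function(i) {
    sel <- bonds[, 1L] == i | bonds[, 2L] == i
    list(atom = ifelse(bonds[sel, 1L] == i, bonds[sel, 2L], bonds[sel, 1L]),
         order = bonds[sel, 3L])
  }
  ## double-bonded neighbours of given element, per atom
  dbl_to <- function(i, elem) {
    nb <- nbrs(i)
    sum(nb$order == 2L & g$elem[nb$atom] == elem)
  }

  changed <- FALSE
  for (i in seq_len(n)) {
    e <- g$elem[i]
    if (e == "O" && charge[i] == 0L && deg[i] == 1L && g$hcount[i] >= 1L) {
      nb <- nbrs(i)
      x <- nb$atom[1L]
      if (nb$order[1L] == 1L) {
        acid <- (g$elem[x] == "C" && !g$arom[x] && dbl_to(x, "O") >= 1L) ||
          (g$elem[x] == "S" && dbl_to(x, "O") >= 2L) ||
          (g$elem[x] == "P" && dbl_to(x, "O") >= 1L)
        if (acid) {
          charge[i] <- -1L
          changed <- TRUE
        }
      }
    } else if (e == "N" && charge[i] == 0L && !g$arom[i]) {
      nb <- nbrs(i)
      if (length(nb$atom) > 0L && all(nb$order == 1L) && deg[i] <= 3L) {
        ## aliphatic amine: no aromatic neighbour, no carbonyl/thiocarbonyl
        ## neighbour (amide), no amidine carbon neighbour
        ok <- TRUE
        for (k in seq_along(nb$atom)) {
          x <- nb$atom[k]
          if (g$arom[x]) ok <- FALSE
          if (g$elem[x] == "C" &&
              (dbl_to(x, "O") >= 1L || dbl_to(x, "S") >= 1L ||
               dbl_to(x, "N") >= 1L)) ok <- FALSE
          if (!g$elem[x] %in% c("C", "H")) ok <- FALSE
        }
        if (ok) {
          charge[i] <- 1L
          changed <- TRUE
        }
      } else if (length(nb$atom) > 0L && any(nb$order == 2L)) {
        ## amidine / guanidine: N=C where C bears >=1 other (single-bonded)
        ## nitrogen; protonate this imine nitrogen
        k <- which(nb$order == 2L)[1L]
        x <- nb$atom[k]
        if (g$elem[x] == "C" && !g$arom[x]) {
          nbx <- nbrs(x)
          other_n <- sum(g$elem[nbx$atom] == "N" & nbx$order == 1L)
          if (other_n >= 1L) {
            charge[i] <- 1L
            changed <- TRUE
          }
        }
      }
    }
  }
  if (changed) charge else NULL
}

## Serialize graphs (with overridden charges) to a V2000 SD block.
.graphs_to_sdf <- function(graphs, charges) {
  blocks <- vapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    q <- charges[[i]]
    n <- length(g$elem)
    nb <- nrow(g$bonds)
    atom_lines <- vapply(seq_len(n), function(a) {
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              0, 0, 0, g$elem[a])
    }, character(1))
    bond_lines <- if (nb > 0L) {
      vapply(seq_len(nb), function(b) {
        sprintf("%3d%3d%3d  0  0  0  0", g$bonds[b, 1L], g$bonds[b, 2L],
                g$bonds[b, 3L])
      }, character(1))
    } else character(0)
    chg <- which(q != 0L)
    chg_lines <- character(0)
    while (length(chg) > 0L) {
      take <- utils::head(chg, 8L)
      chg <- chg[-seq_along(take)]
      chg_lines <- c(chg_lines, paste0(
        "M  CHG", sprintf("%3d", length(take)),
        paste0(sprintf("%4d%4d", take, q[take]), collapse = "")))
    }
    paste(c(sprintf("mol%d", i), "  fpbrowse", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
            atom_lines, bond_lines, chg_lines, "M  END", "$$$$"),
          collapse = "\n")
  }, character(1))
  paste0(paste(blocks, collapse = "\n"), "\n")
}

#' Adjust ionization state to pH 7.4
#'
#' Applies a fixed, documented rule table: carboxylic, sulfonic and
#' phosphonic/phosphoric acids are deprotonated; aliphatic amines and the
#' imine nitrogen of amidines/guanidines are protonated; anilines,
#' amides, alcohols and phenols stay neutral. Full pKa prediction is
#' deliberately out of scope. Output is re-canonicalized.
#'
#' @param smiles character vector of single-fragment SMILES.
#' @return character vector of canonical SMILES at the modelled pH 7.4
#'   protonation state.
#' @export
adjust_ionization_ph74 <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) stop("unparseable SMILES: ", smiles[which(is.na(can))[1L]])
  graphs <- mol_graphs(can)
  new_charges <- lapply(graphs, .ph74_charges)
  hit <- which(!vapply(new_charges, is.null, logical(1)))
  if (length(hit) == 0L) return(can)
  sdf <- .graphs_to_sdf(graphs[hit], new_charges[hit])
  res <- ChemmineOB::convertFormat("SDF", "CAN", source = sdf)
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) != length(hit)) {
    stop("ionization round-trip lost molecules")
  }
  can[hit] <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`,
                     character(1), 1L)
  can
}

#' Full standardization pipeline
#'
#' Counter-ion removal, then pH 7.4 ionization, then canonicalization.
#' Idempotent: standardizing an already-standardized string is a no-op.
#'
#' @param smiles character vector of raw SMILES.
#' @return character vector of standardized canonical SMILES.
#' @export
standardize_smiles <- function(smiles) {
  .standardize_pipeline(smiles)$smiles
}

## Fused pipeline: canonicalize and parse each molecule once, re-parse
## only the ionization-changed subset. Returns canonical smiles plus the
## final graphs, for callers that go on to annotate or fingerprint.
.standardize_pipeline <- function(smiles) {
  can <- strip_counter_ions(smiles)
  graphs <- mol_graphs(can)
  new_charges <- lapply(graphs, .ph74_charges)
  hit <- which(!vapply(new_charges, is.null, logical(1)))
  if (length(hit) > 0L) {
    sdf <- .graphs_to_sdf(graphs[hit], new_charges[hit])
    res <- ChemmineOB::convertFormat("SDF", "CAN", source = sdf)
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    if (length(lines) != length(hit)) stop("ionization round-trip lost molecules")
    can[hit] <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`,
                       character(1), 1L)
    graphs[hit] <- mol_graphs(can[hit])
  }
  list(smiles = can, graphs = graphs)
}

#' Annotate standardized molecules
#'
#' Builds molecule records with Hill formula, hydrogen-bond acceptor count
#' (number of N and O atoms), hydrogen-bond donor count (number of
#' hydrogens on N or O), oxygen and nitrogen counts, and the 9-bit vendor
#' mask.
#'
#' @param smiles character vector of standardized single-fragment SMILES.
#' @param id character vector of identifiers.
#' @param vendor_mask integer vector in `[1, 511]` (bit per vendor);
#'   recycled if length 1.
#' @param graphs optional pre-parsed graphs from [mol_graphs()]; when
#'   given, `smiles` must already be canonical and match them.
#' @return a `mol_records` data frame with one row per molecule.
#' @export
annotate_molecules <- function(smiles, id, vendor_mask = 511L,
                               graphs = NULL) {
  stopifnot(length(smiles) == length(id))
  vendor_mask <- as.integer(rep_len(vendor_mask, length(smiles)))
  if (any(is.na(vendor_mask)) || any(vendor_mask < 1L) ||
      any(vendor_mask > 511L)) {
    stop("vendor_mask must be an integer in [1, 511]")
  }
  if (is.null(graphs)) {
    can <- canonical_smiles(smiles)
    if (anyNA(can)) stop("unparseable SMILES: ", smiles[which(is.na(can))[1L]])
    graphs <- mol_graphs(can)
  } else {
    can <- smiles  # caller guarantees canonical smiles matching graphs
  }
  ann <- vapply(graphs, function(g) {
    is_n <- g$elem == "N"
    is_o <- g$elem == "O"
    c(hba = sum(is_n | is_o),
      hbd = sum(g$hcount[is_n | is_o]),
      n_oxygen = sum(is_o),
      n_nitrogen = sum(is_n))
  }, integer(4))
  out <- data.frame(
    id = as.character(id),
    smiles = can,
    formula = vapply(graphs, graph_formula, character(1)),
    hba = ann["hba", ],
    hbd = ann["hbd", ],
    n_oxygen = ann["n_oxygen", ],
    n_nitrogen = ann["n_nitrogen", ],
    vendor_mask = vendor_mask,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("mol_records", "data.frame")
  out
}

#' Load and standardize a .smi library
#'
#' One record per line: `SMILES id [vendor_mask]`, whitespace-separated;
#' lines starting with `#` are ignored; a missing vendor mask defaults to
#' 511 (all vendors). Malformed lines are skipped with a warning carrying
#' the line number. Standardization (strip counter ions, pH 7.4
#' ionization, annotation) is applied to every record.
#'
#' @param path path to a .smi file.
#' @return a `mol_records` data frame.
#' @export
load_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")

  smi <- vapply(fields, function(f) if (length(f) >= 1L) f[[1L]] else NA,
                character(1))
  ids <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else NA,
                character(1))
  mask <- vapply(fields, function(f) {
    if (length(f) >= 3L) suppressWarnings(as.integer(f[[3L]])) else 511L
  }, integer(1))

  bad <- is.na(ids) | is.na(mask) | mask < 1L | mask > 511L
  can <- rep(NA_character_, length(smi))
  can[!bad & !is.na(smi)] <- canonical_smiles(smi[!bad & !is.na(smi)])
  bad <- bad | is.na(can)
  for (j in which(bad)) {
    warning("skipping malformed line ", lineno[j], ": ", lines[lineno[j]],
            call. = FALSE)
  }
  if (!any(!bad)) stop("no valid records in ", path)

  std <- .standardize_pipeline(can[!bad])
  annotate_molecules(std$smiles, ids[!bad], mask[!bad], graphs = std$graphs)
}

#' Write records to a .smi file
#'
#' @param records a `mol_records` data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_smi <- function(records, path) {
  writeLines(paste(records$smiles, records$id, records$vendor_mask), path)
  invisible(path)
}
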