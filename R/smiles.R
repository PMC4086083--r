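## SMILES layer: canonicalization (OpenBabel via ChemmineOB), a light
## tokenizer, and conversion to an internal molecular-graph list used by
## the annotation and fingerprint code. Graphs are kekulized (bond orders
## 1/2/3); aromatic flags are taken from the lowercase atoms of the
## canonical SMILES, whose atom order matches the SDF atom block.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form. Invalid entries yield `NA`
#' instead of aborting, so callers can skip bad library lines with a
#' warning. Multi-fragment inputs are preserved (fragments stay
#' dot-separated).
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where unparseable.
#' @export
canonical_smiles <- function(smiles) {
  smiles <- as.character(smiles)
  out <- rep(NA_character_, length(smiles))
  todo <- which(!is.na(smiles) & nzchar(trimws(smiles)))
  ## OpenBabel stops a multi-record conversion at the first bad line; feed
  ## the remainder again after marking the offender NA.
  while (length(todo) > 0L) {
    src <- paste0(paste(smiles[todo], todo), "\n", collapse = "")
    res <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", source = src),
                    error = function(e) "")
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    got_idx <- integer(0)
    if (length(lines) > 0L) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      got_idx <- suppressWarnings(as.integer(vapply(parts, function(p) {
        if (length(p) >= 2L) p[[2]] else NA_character_
      }, character(1))))
      keep <- !is.na(got_idx) & got_idx %in% todo
      smi_out <- vapply(parts, `[[`, character(1), 1L)
      out[got_idx[keep]] <- smi_out[keep]
    }
    done <- todo %in% got_idx
    if (all(done)) break
    first_bad <- todo[which(!done)[1L]]
    out[first_bad] <- NA_character_
    todo <- todo[todo > first_bad & !(todo %in% got_idx)]
  }
  out
}

## Symbols counted by the SMILES-character fingerprint (34 entries).
## Two-character element symbols Cl and Br count as single symbols;
## anything outside the table is ignored.
SMIFP_SYMBOLS <- c("C", "c", "N", "n", "O", "o", "S", "s", "P", "F",
                   "Cl", "Br", "I", "B", "H", "(", ")", "[", "]",
                   "=", "#", "-", "+", "/", "\\", "@",
                   "1", "2", "3", "4", "5", "6", "7", "8")

## Split a SMILES string into single symbols, keeping Cl/Br intact.
smiles_symbols <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  syms <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (i < n && ((ch == "C" && chars[i + 1L] == "l") ||
                  (ch == "B" && chars[i + 1L] == "r"))) {
      syms <- c(syms, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      syms <- c(syms, ch)
      i <- i + 1L
    }
  }
  syms
}

## Atom tokens of a SMILES string in order of appearance:
## data.frame(elem, arom). Bracket atoms contribute their element symbol
## (e.g. "[NH3+]" -> N, "[nH]" -> aromatic n).
ELEMENT_TWO <- c("Cl", "Br", "Si", "Se", "As", "Na", "Li", "Mg", "Ca", "Al",
                 "Zn", "Fe", "Cu", "Mn", "Sn", "Ag", "Au", "Te", "Kr", "Xe")
ORGANIC_ONE <- c("B", "C", "N", "O", "P", "S", "F", "I")
AROM_ONE <- c("b", "c", "n", "o", "p", "s")

smiles_atoms <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  elem <- character(0)
  arom <- logical(0)
  charge <- integer(0)
  hexpl <- integer(0)  # bracket H count, NA when implicit
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      body <- sub("^[0-9]+", "", body)  # isotope
      m <- regmatches(body, regexpr("^([A-Z][a-z]?|[a-z])", body))
      if (length(m) == 1L) {
        is_ar <- grepl("^[a-z]", m)
        e <- m
        ## lowercase second letter of a two-char element is fine ("Cl");
        ## a pure-lowercase match is an aromatic organic atom
        if (is_ar) e <- toupper(substr(m, 1L, 1L))
        rest <- substring(body, nchar(m) + 1L)
        hm <- regmatches(rest, regexpr("H[0-9]*", rest))
        hc <- if (length(hm) == 0L) 0L else if (hm == "H") 1L else
          as.integer(substring(hm, 2L))
        q <- 0L
        qm <- regmatches(rest, regexpr("[+-][0-9]*[+-]*", rest))
        if (length(qm) == 1L) {
          sign <- if (substr(qm, 1L, 1L) == "+") 1L else -1L
          num <- regmatches(qm, regexpr("[0-9]+", qm))
          q <- if (length(num) == 1L) sign * as.integer(num) else
            sign * sum(strsplit(qm, "")[[1]] %in% c("+", "-"))
        }
        elem <- c(elem, e)
        arom <- c(arom, is_ar)
        charge <- c(charge, q)
        hexpl <- c(hexpl, hc)
      }
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% ELEMENT_TWO) {
      elem <- c(elem, paste0(ch, chars[i + 1L]))
      arom <- c(arom, FALSE)
      charge <- c(charge, 0L)
      hexpl <- c(hexpl, NA_integer_)
      i <- i + 2L
    } else if (ch %in% ORGANIC_ONE) {
      elem <- c(elem, ch)
      arom <- c(arom, FALSE)
      charge <- c(charge, 0L)
      hexpl <- c(hexpl, NA_integer_)
      i <- i + 1L
    } else if (ch %in% AROM_ONE) {
      elem <- c(elem, toupper(ch))
      arom <- c(arom, TRUE)
      charge <- c(charge, 0L)
      hexpl <- c(hexpl, NA_integer_)
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(elem = elem, arom = arom, charge = charge, hexpl = hexpl,
             stringsAsFactors = FALSE)
}

## Heavy-atom and carbon counts of a SMILES fragment (tokenizer-based;
## explicit [H] excluded from the heavy count).
fragment_atom_counts <- function(smiles) {
  at <- smiles_atoms(smiles)
  heavy <- at$elem[at$elem != "H"]
  c(heavy = length(heavy), carbon = sum(heavy == "C"))
}

## MDL old-style charge codes -> formal charge
.mdl_charge <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

ATOMIC_NUMBER <- c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L,
                   P = 15L, S = 16L, Cl = 17L, Br = 35L, I = 53L,
                   Si = 14L, Se = 34L, Na = 11L, K = 19L, Li = 3L,
                   Mg = 12L, Ca = 20L, Zn = 30L, Fe = 26L, Al = 13L)

## Implicit hydrogen count from a simple valence model on the kekulized
## graph. `bondsum` includes bonds to explicit H atoms.
.implicit_h <- function(elem, charge, bondsum) {
  eff <- switch(elem,
    C = if (charge == 0L) 4L else 3L,
    N = max(0L, min(4L, 3L + charge)),
    O = max(0L, 2L + charge),
    S = max(0L, 2L + charge),
    P = max(0L, 3L + charge),
    B = max(0L, 3L - charge),
    F = , Cl = , Br = , I = if (charge == 0L) 1L else 0L,
    H = max(0L, 1L - abs(charge)),
    0L)
  max(0L, eff - bondsum)
}

#' Parse canonical SMILES into molecular graphs
#'
#' Batch-parses SMILES through OpenBabel and returns one graph per
#' molecule: element symbols, formal charges, aromatic flags, implicit
#' hydrogen counts and a kekulized bond table. Input must already be
#' valid (use [canonical_smiles()] first).
#'
#' @param smiles character vector of parseable SMILES.
#' @return list of graphs; each has `elem`, `charge`, `arom`, `hcount`
#'   (integer vectors) and `bonds` (integer matrix with columns
#'   `from`, `to`, `order`).
#' @export
mol_graphs <- function(smiles) {
  stopifnot(length(smiles) >= 1L, !anyNA(smiles))
  out <- vector("list", length(smiles))

  ## Bond-less molecules (a single atom token) are built straight from
  ## the tokenizer; the MDL reader mangles zero-bond records.
  toks <- lapply(smiles, smiles_atoms)
  single <- vapply(toks, nrow, integer(1)) == 1L
  for (i in which(single)) {
    at <- toks[[i]]
    bonds <- matrix(integer(0), ncol = 3L,
                    dimnames = list(NULL, c("from", "to", "order")))
    hc <- if (is.na(at$hexpl)) .implicit_h(at$elem, at$charge, 0L) else
      at$hexpl
    out[[i]] <- list(elem = at$elem, charge = at$charge, arom = at$arom,
                     hcount = as.integer(hc), bonds = bonds)
  }

  multi <- which(!single)
  if (length(multi) > 0L) {
    nm <- sprintf("m%06d", seq_along(multi))
    sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles[multi], nm))
    abs_ <- ChemmineR::atomblock(sdf)
    bbs <- ChemmineR::bondblock(sdf)
    if (length(abs_) != length(multi)) {
      stop("SMILES parsing dropped molecules; canonicalize and filter first")
    }
    for (j in seq_along(multi)) {
      ab <- abs_[[j]]
      bb <- bbs[[j]]
      elem <- sub("_.*$", "", rownames(ab))
      charge <- if ("C5" %in% colnames(ab)) .mdl_charge(ab[, "C5"]) else
        rep(0L, nrow(ab))
      if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
        bonds <- matrix(integer(0), ncol = 3L,
                        dimnames = list(NULL, c("from", "to", "order")))
      } else {
        bonds <- cbind(from = as.integer(bb[, 1L]), to = as.integer(bb[, 2L]),
                       order = as.integer(bb[, 3L]))
      }
      out[[multi[j]]] <- .finish_graph(elem, charge, bonds, smiles[multi[j]],
                                       toks[[multi[j]]])
    }
  }
  out
}

## Merge explicit H atoms, attach aromatic flags, compute implicit H.
.finish_graph <- function(elem, charge, bonds, smiles, at = NULL) {
  ## aromatic flags from SMILES token order (verified to match the SDF
  ## atom order for OpenBabel output); explicit [H] tokens align too
  if (is.null(at)) at <- smiles_atoms(smiles)
  arom <- if (nrow(at) == length(elem) && all(at$elem == elem)) at$arom else
    rep(FALSE, length(elem))

  expl_h <- rep(0L, length(elem))
  is_h <- elem == "H"
  if (any(is_h)) {
    for (b in seq_len(nrow(bonds))) {
      f <- bonds[b, 1L]; t <- bonds[b, 2L]
      if (is_h[f] && !is_h[t]) expl_h[t] <- expl_h[t] + 1L
      if (is_h[t] && !is_h[f]) expl_h[f] <- expl_h[f] + 1L
    }
    keep <- which(!is_h)
    remap <- match(seq_along(elem), keep)
    bkeep <- !(is_h[bonds[, 1L]] | is_h[bonds[, 2L]])
    bonds <- bonds[bkeep, , drop = FALSE]
    bonds[, 1L] <- remap[bonds[, 1L]]
    bonds[, 2L] <- remap[bonds[, 2L]]
    elem <- elem[keep]; charge <- charge[keep]
    arom <- arom[keep]; expl_h <- expl_h[keep]
  }

  n <- length(elem)
  bondsum <- rep(0L, n)
  if (nrow(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      o <- bonds[b, 3L]
      bondsum[bonds[b, 1L]] <- bondsum[bonds[b, 1L]] + o
      bondsum[bonds[b, 2L]] <- bondsum[bonds[b, 2L]] + o
    }
  }
  hcount <- vapply(seq_len(n), function(i) {
    .implicit_h(elem[i], charge[i], bondsum[i]) + expl_h[i]
  }, integer(1))

  list(elem = elem, charge = as.integer(charge), arom = arom,
       hcount = hcount, bonds = bonds)
}

## Heavy-atom degree per atom.
.graph_degree <- function(g) {
  deg <- rep(0L, length(g$elem))
  if (nrow(g$bonds) > 0L) {
    tab <- tabulate(c(g$bonds[, 1L], g$bonds[, 2L]), nbins = length(g$elem))
    deg <- as.integer(tab)
  }
  deg
}

## Ring information via the compiled SSSR/bridge routines.
.graph_rings <- function(g) {
  cpp_ring_info(length(g$elem), as.integer(g$bonds[, 1L]),
                as.integer(g$bonds[, 2L]))
}

#' Hill-order molecular formula of a graph
#'
#' Carbon first, hydrogen second, remaining elements alphabetical; a net
#' formal charge is appended as a suffix (e.g. `"C2H3O2-"`) so charged
#' and neutral species never share a formula.
#'
#' @param g molecular graph from [mol_graphs()].
#' @return formula string.
#' @keywords internal
graph_formula <- function(g) {
  counts <- table(g$elem)
  nh <- sum(g$hcount)
  parts <- character(0)
  fmt <- function(e, k) if (k == 1L) e else paste0(e, k)
  if ("C" %in% names(counts)) {
    parts <- c(parts, fmt("C", counts[["C"]]))
    if (nh > 0L) parts <- c(parts, fmt("H", nh))
    rest <- sort(setdiff(names(counts), "C"))
  } else {
    rest <- sort(names(counts))
    if (nh > 0L) rest <- sort(c(rest, "H"))
  }
  for (e in rest) {
    k <- if (e == "H" && !("H" %in% names(counts))) nh else
      counts[[e]] + if (e == "H") nh else 0L
    parts <- c(parts, fmt(e, k))
  }
  f <- paste(parts, collapse = "")
  q <- sum(g$charge)
  if (q != 0L) {
    f <- paste0(f, if (abs(q) > 1L) abs(q) else "", if (q > 0L) "+" else "-")
  }
  f
}
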