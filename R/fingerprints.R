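## The four fingerprint spaces. All encoders are pure functions of the
## canonical structure: inputs are canonicalized before encoding, so any
## SMILES spelling of a molecule yields the same vector.
##
##   sfp    1024-bit hashed substructure fingerprint, linear atom-bond
##          paths of 0..7 bonds
##   ecfp4  1024-bit extended-connectivity fingerprint, bond diameter 4
##          (circular environments of radius 0..2)
##   mqn    42 molecular quantum number counts
##   smifp  34 SMILES character counts
##
## The vector total sum doubles as the hash key of the search index.

#' Fingerprint space names
#' @export
FP_SPACES <- c("sfp", "ecfp4", "mqn", "smifp")

#' Dimensions of each fingerprint space
#' @export
FP_LENGTHS <- c(sfp = 1024L, ecfp4 = 1024L, mqn = 42L, smifp = 34L)

## Component names of the 42 MQN counts, in output order.
MQN_NAMES <- c(
  "c", "f", "cl", "br", "i", "s", "p", "an", "cn", "ao", "co", "hac",
  "asb", "adb", "atb", "csb", "cdb", "ctb", "rbc",
  "hbam", "hba", "hbdm", "hbd", "neg", "pos",
  "amv", "adv", "atv", "aqv", "cdv", "ctv", "cqv",
  "r3", "r4", "r5", "r6", "r7", "r8", "r9", "rg10", "afr", "bfr")

.fpvec <- function(space, values) {
  structure(list(space = space, values = as.integer(values),
                 total_sum = as.integer(sum(values))),
            class = "fpvec")
}

#' @export
print.fpvec <- function(x, ...) {
  cat(sprintf("<fingerprint %s: %d dims, total sum %d>\n",
              x$space, length(x$values), x$total_sum))
  invisible(x)
}

## ---- MQN ------------------------------------------------------------------
## 12 atom counts, 7 bond counts, 6 polarity counts, 17 topology counts on
## the kekulized molecular graph (aromatic rings count as alternating
## single/double bonds).
.fp_mqn_graph <- function(g) {
  n <- length(g$elem)
  deg <- .graph_degree(g)
  ri <- .graph_rings(g)
  bond_cyc <- ri$bond_cyclic
  atom_cyc <- rep(FALSE, n)
  if (nrow(g$bonds) > 0L && any(bond_cyc)) {
    atom_cyc[unique(c(g$bonds[bond_cyc, 1L], g$bonds[bond_cyc, 2L]))] <- TRUE
  }

  is_n <- g$elem == "N"; is_o <- g$elem == "O"
  v <- integer(42)
  names(v) <- MQN_NAMES
  v["c"] <- sum(g$elem == "C")
  v["f"] <- sum(g$elem == "F")
  v["cl"] <- sum(g$elem == "Cl")
  v["br"] <- sum(g$elem == "Br")
  v["i"] <- sum(g$elem == "I")
  v["s"] <- sum(g$elem == "S")
  v["p"] <- sum(g$elem == "P")
  v["an"] <- sum(is_n & !atom_cyc)
  v["cn"] <- sum(is_n & atom_cyc)
  v["ao"] <- sum(is_o & !atom_cyc)
  v["co"] <- sum(is_o & atom_cyc)
  v["hac"] <- n

  ord <- g$bonds[, 3L]
  if (nrow(g$bonds) > 0L) {
    v["asb"] <- sum(ord == 1L & !bond_cyc)
    v["adb"] <- sum(ord == 2L & !bond_cyc)
    v["atb"] <- sum(ord == 3L & !bond_cyc)
    v["csb"] <- sum(ord == 1L & bond_cyc)
    v["cdb"] <- sum(ord == 2L & bond_cyc)
    v["ctb"] <- sum(ord == 3L & bond_cyc)
    v["rbc"] <- .rotatable_bonds(g, deg, bond_cyc)
  }

  ## polarity: lone pairs LP = (valence electrons - charge - bonds)/2
  ve <- c(N = 5L, O = 6L)
  bondsum <- rep(0L, n)
  if (nrow(g$bonds) > 0L) {
    for (b in seq_len(nrow(g$bonds))) {
      bondsum[g$bonds[b, 1L]] <- bondsum[g$bonds[b, 1L]] + g$bonds[b, 3L]
      bondsum[g$bonds[b, 2L]] <- bondsum[g$bonds[b, 2L]] + g$bonds[b, 3L]
    }
  }
  lp <- integer(n)
  no <- which(is_n | is_o)
  for (i in no) {
    lp[i] <- max(0L, (ve[[g$elem[i]]] - g$charge[i] -
                        (bondsum[i] + g$hcount[i])) %/% 2L)
  }
  v["hbam"] <- sum(lp[no])                      # acceptor sites (lone pairs)
  v["hba"] <- sum(lp[no] > 0L)                  # acceptor atoms
  v["hbdm"] <- sum(g$hcount[no])                # donor sites (N/O hydrogens)
  v["hbd"] <- sum(g$hcount[no] > 0L)            # donor atoms
  v["neg"] <- sum(g$charge < 0L)
  v["pos"] <- sum(g$charge > 0L)

  degc <- pmin(deg, 4L)
  v["amv"] <- sum(degc == 1L & !atom_cyc)
  v["adv"] <- sum(degc == 2L & !atom_cyc)
  v["atv"] <- sum(degc == 3L & !atom_cyc)
  v["aqv"] <- sum(degc == 4L & !atom_cyc)
  v["cdv"] <- sum(degc == 2L & atom_cyc)
  v["ctv"] <- sum(degc == 3L & atom_cyc)
  v["cqv"] <- sum(degc == 4L & atom_cyc)

  rs <- ri$ring_sizes
  for (k in 3:9) v[sprintf("r%d", k)] <- sum(rs == k)
  v["rg10"] <- sum(rs >= 10L)
  v["afr"] <- sum(ri$atom_rings >= 2L)
  v["bfr"] <- sum(ri$bond_rings >= 2L)
  v
}

## Rotatable bond: acyclic single bond between two non-terminal heavy
## atoms, excluding amide C-N.
.rotatable_bonds <- function(g, deg, bond_cyc) {
  b <- g$bonds
  cand <- which(b[, 3L] == 1L & !bond_cyc &
                  deg[b[, 1L]] >= 2L & deg[b[, 2L]] >= 2L)
  if (length(cand) == 0L) return(0L)
  has_carbonyl <- vapply(seq_along(g$elem), function(i) {
    if (g$elem[i] != "C") return(FALSE)
    sel <- (b[, 1L] == i | b[, 2L] == i) & b[, 3L] == 2L
    any(g$elem[ifelse(b[sel, 1L] == i, b[sel, 2L], b[sel, 1L])] == "O")
  }, logical(1))
  amide <- vapply(cand, function(e) {
    i <- b[e, 1L]; j <- b[e, 2L]
    (g$elem[i] == "N" && has_carbonyl[j]) ||
      (g$elem[j] == "N" && has_carbonyl[i])
  }, logical(1))
  sum(!amide)
}

## ---- SMIfp ----------------------------------------------------------------
.fp_smifp_string <- function(can_smiles) {
  syms <- smiles_symbols(can_smiles)
  v <- vapply(SMIFP_SYMBOLS, function(s) sum(syms == s), integer(1))
  names(v) <- SMIFP_SYMBOLS
  v
}

## ---- sFP ------------------------------------------------------------------
.sfp_atom_tokens <- function(g) {
  tok <- g$elem
  tok[g$arom] <- tolower(tok[g$arom])
  q <- g$charge
  tok[q > 0L] <- paste0(tok[q > 0L], strrep("+", q[q > 0L]))
  tok[q < 0L] <- paste0(tok[q < 0L], strrep("-", -q[q < 0L]))
  tok
}

.fp_sfp_graph <- function(g, max_path = 7L, nbits = 1024L) {
  cpp_sfp(.sfp_atom_tokens(g), as.integer(g$bonds[, 1L]),
          as.integer(g$bonds[, 2L]), as.integer(g$bonds[, 3L]),
          as.integer(max_path), as.integer(nbits))
}

## ---- ECFP4 ----------------------------------------------------------------
.fp_ecfp_graph <- function(g, diameter = 4L, nbits = 1024L) {
  n <- length(g$elem)
  deg <- .graph_degree(g)
  ri <- .graph_rings(g)
  atom_cyc <- rep(FALSE, n)
  if (nrow(g$bonds) > 0L && any(ri$bond_cyclic)) {
    atom_cyc[unique(c(g$bonds[ri$bond_cyclic, 1L],
                      g$bonds[ri$bond_cyclic, 2L]))] <- TRUE
  }
  z <- unname(ATOMIC_NUMBER[g$elem])
  z[is.na(z)] <- 0L
  inv <- cbind(z, deg, g$hcount, g$charge, as.integer(g$arom),
               as.integer(atom_cyc))
  storage.mode(inv) <- "integer"
  cpp_ecfp(inv, as.integer(g$bonds[, 1L]), as.integer(g$bonds[, 2L]),
           as.integer(g$bonds[, 3L]), as.integer(diameter %/% 2L),
           as.integer(nbits))
}

## ---- public API -----------------------------------------------------------

#' Compute a fingerprint
#'
#' @param x a SMILES string, or a single-row `mol_records` data frame.
#' @param space one of `"sfp"`, `"ecfp4"`, `"mqn"`, `"smifp"`.
#' @param max_path maximum path length in bonds for the substructure
#'   fingerprint (default 7).
#' @param diameter bond diameter for the extended-connectivity
#'   fingerprint (default 4, i.e. radius 2).
#' @return an `fpvec`: list with `space`, integer `values` and
#'   `total_sum` (the index hash key).
#' @export
fingerprint <- function(x, space = c("sfp", "ecfp4", "mqn", "smifp"),
                        max_path = 7L, diameter = 4L) {
  space <- match.arg(space)
  smi <- if (is.data.frame(x)) x$smiles[1L] else as.character(x)[1L]
  m <- fingerprint_matrix(smi, space, max_path = max_path,
                          diameter = diameter)
  .fpvec(space, m$values[1L, ])
}

#' Compute fingerprints for many molecules at once
#'
#' @param smiles character vector of SMILES (canonicalized internally),
#'   or a `mol_records` data frame.
#' @inheritParams fingerprint
#' @param graphs optional pre-parsed graphs from [mol_graphs()] (must
#'   match canonical `smiles`), to avoid re-parsing.
#' @param assume_canonical skip re-canonicalization; set only when
#'   `smiles` are known canonical (e.g. from a `mol_records` built by
#'   this package). Passing a data frame implies it.
#' @return list with `space`, integer matrix `values` (one row per
#'   molecule) and integer vector `total_sum`.
#' @export
fingerprint_matrix <- function(smiles, space = c("sfp", "ecfp4", "mqn", "smifp"),
                               max_path = 7L, diameter = 4L, graphs = NULL,
                               assume_canonical = FALSE) {
  space <- match.arg(space)
  if (is.data.frame(smiles)) {
    smiles <- smiles$smiles
    assume_canonical <- TRUE
  }
  if (assume_canonical || !is.null(graphs)) {
    can <- smiles
  } else {
    can <- canonical_smiles(smiles)
    if (anyNA(can)) stop("unparseable SMILES: ", smiles[which(is.na(can))[1L]])
  }
  if (space == "smifp") {
    values <- t(vapply(can, .fp_smifp_string, integer(34L)))
  } else {
    if (is.null(graphs)) graphs <- mol_graphs(can)
    values <- switch(space,
      mqn = t(vapply(graphs, .fp_mqn_graph, integer(42L))),
      sfp = t(vapply(graphs, .fp_sfp_graph, integer(1024L),
                     max_path = max_path)),
      ecfp4 = t(vapply(graphs, .fp_ecfp_graph, integer(1024L),
                       diameter = diameter)))
  }
  rownames(values) <- NULL
  list(space = space, values = values,
       total_sum = as.integer(rowSums(values)))
}

#' Write a fingerprint dump TSV
#'
#' Columns: `id`, `space`, `total_sum`, `values`; binary spaces are
#' serialized as a 1024-character 0/1 string, count spaces as
#' comma-separated integers.
#'
#' @param ids character vector of identifiers.
#' @param fps result of [fingerprint_matrix()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fingerprints <- function(ids, fps, path) {
  binary <- fps$space %in% c("sfp", "ecfp4")
  val <- apply(fps$values, 1L, function(v) {
    if (binary) paste(v, collapse = "") else paste(v, collapse = ",")
  })
  df <- data.frame(id = ids, space = fps$space, total_sum = fps$total_sum,
                   values = val, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fingerprint dump TSV
#'
#' @param path path written by [write_fingerprints()].
#' @return list with `ids` and a [fingerprint_matrix()]-shaped list.
#' @export
read_fingerprints <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  space <- df$space[1L]
  if (space %in% c("sfp", "ecfp4")) {
    values <- t(vapply(strsplit(df$values, ""),
                       function(v) as.integer(v), integer(FP_LENGTHS[[space]])))
  } else {
    values <- t(vapply(strsplit(df$values, ",", fixed = TRUE),
                       function(v) as.integer(v), integer(FP_LENGTHS[[space]])))
  }
  rownames(values) <- NULL
  list(ids = df$id,
       fps = list(space = space, values = values,
                  total_sum = as.integer(df$total_sum)))
}
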