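# Enumeration and canonicalization of H/Cl/Br substitution patterns of the
# dibenzo-p-dioxin skeleton.  Substitutable ring positions are numbered
# 1,2,3,4,6,7,8,9 (IUPAC); positions 5 and 10 are the ring oxygens.  A
# congener is an 8-tuple over {H, Cl, Br} in that fixed position order.

#' Substitutable ring positions of dibenzo-p-dioxin
#'
#' The eight carbon positions of the dibenzo-p-dioxin skeleton that can carry
#' a substituent, in the fixed order used throughout the package.
#'
#' @return Integer vector `c(1, 2, 3, 4, 6, 7, 8, 9)`.
#' @export
dioxin_positions <- function() c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L)

#' Allowed substituent states, in canonical sort order
#'
#' Ordering is H < Cl < Br; the canonical representative of a symmetry orbit
#' is the lexicographic minimum under this ordering.
#'
#' @return Character vector `c("H", "Cl", "Br")`.
#' @export
substituent_alphabet <- function() c("H", "Cl", "Br")

# internal: encode/decode between substituent symbols and ranks 0,1,2
.sub_rank <- function(state) {
  r <- match(state, substituent_alphabet()) - 1L
  if (anyNA(r)) {
    stop("invalid substituent symbol(s): ",
         paste(unique(state[is.na(r)]), collapse = ", "))
  }
  r
}

.check_state <- function(state) {
  if (!is.character(state) || length(state) != 8L) {
    stop("a congener state must be a character vector of length 8 over {H, Cl, Br}")
  }
  invisible(.sub_rank(state))
}

#' Symmetry group of the dibenzo-p-dioxin skeleton
#'
#' The planar tricyclic skeleton has an order-4 in-plane symmetry group acting
#' on the eight substitutable positions: the identity, the mirror across the
#' long (x) axis, the mirror across the short in-plane (y) axis, and the
#' two-fold rotation.  In cycle notation on the position labels these are
#' `e`, `(1 4)(2 3)(6 9)(7 8)`, `(1 6)(2 7)(3 8)(4 9)` and
#' `(1 9)(2 8)(3 7)(4 6)`.  The two position orbits are the "lateral"
#' positions {2,3,7,8} and the "axial" positions {1,4,6,9} along the y axis.
#'
#' @return An object of class `dioxin_symmetry_group`: a list of four integer
#'   permutations of `1:8` (indices into the fixed position order), named
#'   `identity`, `mirror_x`, `mirror_y`, `rotation_2`.
#' @examples
#' g <- dioxin_symmetry_group()
#' length(g)  # 4
#' @export
dioxin_symmetry_group <- function() {
  g <- list(
    identity   = 1:8,
    mirror_x   = c(4L, 3L, 2L, 1L, 8L, 7L, 6L, 5L),  # (1 4)(2 3)(6 9)(7 8)
    mirror_y   = c(5L, 6L, 7L, 8L, 1L, 2L, 3L, 4L),  # (1 6)(2 7)(3 8)(4 9)
    rotation_2 = c(8L, 7L, 6L, 5L, 4L, 3L, 2L, 1L)   # (1 9)(2 8)(3 7)(4 6)
  )
  class(g) <- "dioxin_symmetry_group"
  g
}

#' @export
print.dioxin_symmetry_group <- function(x, ...) {
  cat("Dibenzo-p-dioxin skeleton symmetry group (order", length(x), ")\n")
  labs <- dioxin_positions()
  for (nm in names(x)) {
    cat(sprintf("  %-10s positions -> %s\n", nm,
                paste(labs[x[[nm]]], collapse = " ")))
  }
  invisible(x)
}

#' Canonical representative of a congener's symmetry orbit
#'
#' Applies each group permutation to the state and returns the lexicographic
#' minimum under the ordering H < Cl < Br.  Idempotent; every member of one
#' symmetry orbit maps to the same representative.
#'
#' @param state Character vector of length 8 over `{H, Cl, Br}`, ordered by
#'   position (1,2,3,4,6,7,8,9).
#' @param group A `dioxin_symmetry_group` (default: [dioxin_symmetry_group()]).
#' @return The canonical state (character vector of length 8).
#' @examples
#' canonicalize(c("H","Cl","Cl","H","H","Cl","Cl","H"))  # 2,3,7,8-tetra-Cl: fixed point
#' @export
canonicalize <- function(state, group = dioxin_symmetry_group()) {
  r <- .check_state(state)
  best <- r
  for (perm in group[-1]) {
    cand <- r[perm]
    # lexicographic comparison of rank vectors
    d <- cand - best
    nz <- which(d != 0L)
    if (length(nz) && d[nz[1L]] < 0L) best <- cand
  }
  substituent_alphabet()[best + 1L]
}

#' All members of a congener's symmetry orbit
#'
#' @inheritParams canonicalize
#' @return Character matrix with one distinct orbit member per row (1, 2 or 4
#'   rows for this group).
#' @export
symmetry_orbit <- function(state, group = dioxin_symmetry_group()) {
  .check_state(state)
  imgs <- unique(t(vapply(group, function(p) state[p], character(8))))
  rownames(imgs) <- NULL
  imgs
}

#' Enumerate all symmetry-distinct congeners
#'
#' Walks all `k^8` raw substitution patterns over the supplied alphabet,
#' canonicalizes each under the skeleton symmetry group, and returns one
#' representative per orbit in lexicographic order (H < Cl < Br; the
#' unsubstituted parent comes first).  With the full `{H, Cl, Br}` alphabet
#' this yields the 1,701 bromo/chloro/mixed congeners; restricting to
#' `{H, Cl}` yields the 76 chlorinated congeners (parent included), in
#' agreement with Burnside's lemma: (k^8 + 3 k^4) / 4.
#'
#' @param group A `dioxin_symmetry_group`.
#' @param alphabet Subset of `c("H","Cl","Br")` to substitute with.
#' @return Character matrix, one canonical congener per row, 8 columns named
#'   `pos1, pos2, ..., pos9`.
#' @examples
#' nrow(enumerate_congeners())                       # 1701
#' nrow(enumerate_congeners(alphabet = c("H","Cl"))) # 76
#' @export
enumerate_congeners <- function(group = dioxin_symmetry_group(),
                                alphabet = substituent_alphabet()) {
  alphabet <- match.arg(alphabet, substituent_alphabet(), several.ok = TRUE)
  ranks <- sort(.sub_rank(alphabet))
  k <- length(ranks)
  n <- k^8
  # all raw patterns as an n x 8 integer matrix of ranks (position 1 is the
  # most significant digit so that row order is lexicographic)
  idx <- 0:(n - 1L)
  raw <- matrix(0L, n, 8L)
  for (j in 8:1) {
    raw[, j] <- ranks[(idx %% k) + 1L]
    idx <- idx %/% k
  }
  # canonical key = minimum base-3 encoding over the group images
  pow <- 3^(7:0)
  key <- raw %*% pow
  for (perm in group[-1]) key <- pmin(key, raw[, perm, drop = FALSE] %*% pow)
  can <- sort(unique(as.vector(key)))
  # decode keys back to states
  out <- matrix("", length(can), 8L,
                dimnames = list(NULL, paste0("pos", dioxin_positions())))
  rem <- can
  for (j in 1:8) {
    d <- rem %/% pow[j]
    out[, j] <- substituent_alphabet()[d + 1L]
    rem <- rem - d * pow[j]
  }
  out
}

#' IUPAC-style congener name
#'
#' Builds names such as `"2,3,7,8-tetrachlorodibenzo-p-dioxin"`: locants
#' sorted ascending within each halogen, substituent prefixes in alphabetical
#' order (bromo before chloro), multiplicative prefixes di/tri/..., and the
#' parent compound named `"dibenzo-p-dioxin"`.
#'
#' Following IUPAC practice, the skeleton numbering is chosen among the
#' symmetry-equivalent renumberings so that the substituted positions get the
#' lowest possible locants (ties broken in favour of low locants for the
#' substituent cited first alphabetically, i.e. bromo).  The name is therefore
#' constant on a symmetry orbit and injective across orbits, even though the
#' stored canonical tuple may use a different (lexicographic-minimum)
#' numbering.
#'
#' @param state Character vector of length 8 over `{H, Cl, Br}`.
#' @param group A `dioxin_symmetry_group` used for the renumbering.
#' @return A single name string.
#' @examples
#' congener_name(c("H","Cl","Cl","H","H","Cl","Cl","H"))
#' @export
congener_name <- function(state, group = dioxin_symmetry_group()) {
  .check_state(state)
  pos <- dioxin_positions()
  # pick the orbit image with IUPAC-lowest locants
  imgs <- lapply(group, function(p) state[p])
  keyfun <- function(s) {
    c(pos[s != "H"], pos[s == "Br"], pos[s == "Cl"])
  }
  best <- imgs[[1L]]
  bestkey <- keyfun(best)
  for (s in imgs[-1L]) {
    k <- keyfun(s)
    d <- k - bestkey  # keys of orbit images have equal lengths
    nz <- which(d != 0)
    if (length(nz) && d[nz[1L]] < 0) {
      best <- s
      bestkey <- k
    }
  }
  state <- best
  mult <- c("", "di", "tri", "tetra", "penta", "hexa", "hepta", "octa")
  prefixes <- c(Br = "bromo", Cl = "chloro")  # alphabetical order
  parts <- character(0)
  for (sym in names(prefixes)) {
    locs <- pos[state == sym]
    if (length(locs)) {
      parts <- c(parts, paste0(paste(locs, collapse = ","), "-",
                               mult[length(locs)], prefixes[[sym]]))
    }
  }
  if (!length(parts)) return("dibenzo-p-dioxin")
  paste0(paste(parts, collapse = "-"), "dibenzo-p-dioxin")
}

#' Is a congener laterally substituted?
#'
#' TRUE iff positions 2, 3, 7 and 8 (the lateral positions associated with
#' AhR-mediated toxicity) all carry a halogen.
#'
#' @inheritParams canonicalize
#' @return Logical flag.
#' @export
is_laterally_substituted <- function(state) {
  .check_state(state)
  all(state[c(2L, 3L, 6L, 7L)] != "H")  # tuple indices of positions 2,3,7,8
}

#' SMILES string for a congener
#'
#' Substitutes halogens into a fixed SMILES template of the dibenzo-p-dioxin
#' skeleton.  Atom order in the template follows positions
#' 1,2,3,4,(4a),O,(5a),6,7,8,9,(9a),O,(10a); states in one symmetry orbit
#' yield SMILES of the same molecular graph.
#'
#' @inheritParams canonicalize
#' @return A SMILES string.
#' @examples
#' to_smiles(rep("H", 8))  # parent skeleton
#' @export
to_smiles <- function(state) {
  .check_state(state)
  br <- ifelse(state == "H", "", paste0("(", state, ")"))
  paste0("c1", br[1], "c", br[2], "c", br[3], "c", br[4],
         "c2Oc3c", br[5], "c", br[6], "c", br[7], "c", br[8],
         "c3Oc12")
}

#' Full congener table
#'
#' Enumerates the congener set and assembles the bookkeeping table used by
#' the rest of the pipeline: names, SMILES, halogen counts and the lateral
#' substitution flag.  Row order is the package's canonical enumeration
#' order, so the `index` column is a stable congener identifier.
#'
#' @inheritParams enumerate_congeners
#' @return `data.frame` with columns `index`, `canonical_tuple` (states joined
#'   by `"."`), `name`, `smiles`, `n_Br`, `n_Cl`, `n_H`, `lateral_flag`.
#' @export
congener_table <- function(group = dioxin_symmetry_group(),
                           alphabet = substituent_alphabet()) {
  states <- enumerate_congeners(group, alphabet)
  n <- nrow(states)
  data.frame(
    index = seq_len(n),
    canonical_tuple = apply(states, 1L, paste, collapse = "."),
    name = apply(states, 1L, congener_name),
    smiles = apply(states, 1L, to_smiles),
    n_Br = rowSums(states == "Br"),
    n_Cl = rowSums(states == "Cl"),
    n_H = rowSums(states == "H"),
    lateral_flag = apply(states, 1L, is_laterally_substituted),
    stringsAsFactors = FALSE
  )
}

#' Recover the state matrix from a congener table
#'
#' @param table A `congener_table()` data frame.
#' @return Character matrix of states (one row per congener).
#' @export
congener_states <- function(table) {
  out <- do.call(rbind, strsplit(table$canonical_tuple, ".", fixed = TRUE))
  colnames(out) <- paste0("pos", dioxin_positions())
  out
}

#' Write a congener table to CSV
#'
#' @param table A `congener_table()` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_congener_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
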