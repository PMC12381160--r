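# Compare model attention with crystal-structure contacts: neighbour
# extraction at a distance cutoff and per-head neighbour/non-neighbour
# attention statistics against the uniform baseline.

#' Find atom-pair contacts in a structure
#'
#' All unordered heavy-atom pairs within the cutoff (3.5 Angstrom by
#' default). Tokens of the model are heavy atoms only, so contacts are
#' computed between heavy atoms; intermolecular pairs (substrate-agent) are
#' flagged when a [SaltComplex-class] is supplied. Periodic/symmetry images
#' are out of scope: the coordinates are taken as a single asymmetric-unit
#' molecule pair.
#'
#' @param structure a [SaltComplex-class] or [Molecule3D-class]
#' @param cutoff contact distance cutoff, Angstrom
#' @param tokens character vector of token atom ids (defining the model's
#'   token order); all heavy atoms of the structure must be mapped
#' @return data.frame with `i`, `j` (token indices, i < j), `atom_i`,
#'   `atom_j`, `distance`, `intermolecular`; cutoff kept as an attribute
#' @export
findContacts <- function(structure, cutoff = 3.5, tokens = NULL) {
  co <- coordsOf(structure)
  el <- elementsOf(structure)
  ids <- atomIds(structure)
  inter <- if (is(structure, "SaltComplex")) {
    rep(c(FALSE, TRUE), c(nAtoms(structure@substrate), nAtoms(structure@agent)))
  } else rep(FALSE, length(el))
  heavy <- el != "H"
  co <- co[heavy, , drop = FALSE]
  ids <- ids[heavy]
  inter <- inter[heavy]
  if (is.null(tokens)) tokens <- ids
  tok <- match(ids, tokens)
  if (anyNA(tok))
    stop("atom(s) not mapped to model tokens: ",
         paste(ids[is.na(tok)], collapse = ", "), call. = FALSE)
  d <- as.matrix(stats::dist(co))
  sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  out <- data.frame(
    i = pmin(tok[sel[, 1]], tok[sel[, 2]]),
    j = pmax(tok[sel[, 1]], tok[sel[, 2]]),
    atom_i = ids[sel[, 1]], atom_j = ids[sel[, 2]],
    distance = d[sel],
    intermolecular = inter[sel[, 1]] != inter[sel[, 2]],
    stringsAsFactors = FALSE)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "n_tokens") <- length(tokens)
  out
}

symmetriseAttention <- function(A) (A + t(A)) / 2

#' Per-head neighbour vs non-neighbour attention statistics
#'
#' For every (stream, block, head) the attention matrix is symmetrised as
#' `(A + t(A)) / 2`, then averaged separately over contact pairs and
#' non-contact off-diagonal pairs; both means are reported as ratios to the
#' uniform baseline `1/T` (a uniform attention matrix gives ratio exactly 1).
#'
#' @param attention attention record from
#'   [modelForward()]`(recordAttention = TRUE)`
#' @param contacts a contact table from [findContacts()] with token indices
#'   matching the attention token set
#' @return data.frame with `stream`, `block`, `head`, `mean_neighbour`,
#'   `mean_nonneighbour`, `ratio_neighbour`, `ratio_nonneighbour`
#' @export
headStats <- function(attention, contacts) {
  if (nrow(contacts) == 0L) stop("empty contact set", call. = FALSE)
  Tn <- length(attention$atoms)
  nb <- matrix(FALSE, Tn, Tn)
  nb[cbind(contacts$i, contacts$j)] <- TRUE
  nb[cbind(contacts$j, contacts$i)] <- TRUE
  off <- !diag(TRUE, Tn)
  rows <- list()
  for (stream in names(attention$streams)) {
    blocks <- attention$streams[[stream]]
    for (b in seq_along(blocks)) {
      for (h in seq_along(blocks[[b]])) {
        M <- symmetriseAttention(blocks[[b]][[h]])
        mn <- mean(M[nb & off])
        mo <- mean(M[!nb & off])
        rows[[length(rows) + 1L]] <- data.frame(
          stream = stream, block = b, head = h,
          mean_neighbour = mn, mean_nonneighbour = mo,
          ratio_neighbour = mn * Tn, ratio_nonneighbour = mo * Tn,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Attention profile of a reference atom
#'
#' The symmetrised attention row of the reference atom (averaged over the
#' requested heads/blocks of one stream), renormalised to sum to one, with
#' the highest-attention partner reported and ties flagged.
#'
#' @param attention attention record from [modelForward()]
#' @param atom reference atom id (must be a token)
#' @param stream `"mean"` or `"diff"`
#' @param block,head indices selecting one attention matrix
#' @param tol tie tolerance on the normalised weights
#' @return list with `profile` (named weights), `argmax` (atom ids of all
#'   maxima) and `tied` (logical)
#' @export
referenceAtomProfile <- function(attention, atom, stream = "mean", block = 1L,
                                 head = 1L, tol = 1e-9) {
  i <- match(atom, attention$atoms)
  if (is.na(i)) stop("atom ", atom, " is not a model token", call. = FALSE)
  M <- symmetriseAttention(attention$streams[[stream]][[block]][[head]])
  row <- M[i, ]
  row <- row / sum(row)
  names(row) <- attention$atoms
  others <- row[-i]
  top <- which(others >= max(others) - tol)
  list(profile = row, argmax = names(others)[top], tied = length(top) > 1L)
}
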