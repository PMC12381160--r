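#' Construct a Molecule3D
#'
#' @param elements character vector of element symbols.
#' @param coords N x 3 numeric matrix, Angstrom.
#' @param role `"substrate"` or `"resolving_agent"`.
#' @param atomIds optional stable atom identifiers; defaults to
#'   `<role prefix>_<index>`.
#' @return a [Molecule3D-class]
#' @export
molecule3d <- function(elements, coords, role = "substrate", atomIds = NULL) {
  elements <- canonicalElement(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(atomIds)) {
    prefix <- if (role == "substrate") "sub" else "agt"
    atomIds <- paste0(prefix, "_", seq_along(elements))
  }
  new("Molecule3D", elements = elements, coords = coords, role = role,
      atomIds = as.character(atomIds))
}

#' Construct a SaltComplex
#'
#' @param substrate,agent [Molecule3D-class] objects with the matching roles.
#' @param handedness `"R"` or `"S"` substrate enantiomer.
#' @return a [SaltComplex-class]
#' @export
saltComplex <- function(substrate, agent, handedness = "R") {
  new("SaltComplex", substrate = substrate, agent = agent,
      handedness = handedness)
}

#' Read a molecular structure from XYZ or SDF (V2000)
#'
#' @param path file path.
#' @param format `"xyz"` or `"sdf"`; guessed from the extension by default.
#' @param role role assigned to the molecule.
#' @return a [Molecule3D-class]
#' @export
readStructure <- function(path, format = c("auto", "xyz", "sdf"),
                          role = "substrate") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.sdf$|\\.mol$", path, ignore.case = TRUE)) "sdf" else "xyz"
  if (format == "xyz") {
    blocks <- parseXyzBlocks(readLines(path), path)
    if (length(blocks) != 1L)
      stop("expected a single-frame XYZ, got ", length(blocks), " frames: ",
           path, call. = FALSE)
    b <- blocks[[1]]
    molecule3d(b$elements, b$coords, role = role)
  } else {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
    if (length(sdf) < 1L) stop("no molecule block found in SDF: ", path, call. = FALSE)
    ab <- ChemmineR::atomblock(sdf[[1]])
    sym <- canonicalElement(sub("_.*$", "", rownames(ab)))
    molecule3d(sym, ab[, 1:3, drop = FALSE], role = role)
  }
}

# Parse concatenated XYZ blocks: natoms line, comment, atom lines.
parseXyzBlocks <- function(lines, path = "<xyz>") {
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("malformed XYZ at line ", i, " (expected atom count): ", path,
           call. = FALSE)
    if (i + 1L + n > length(lines))
      stop("truncated XYZ block starting at line ", i, ": ", path, call. = FALSE)
    comment <- lines[i + 1L]
    rows <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(rows), "[[:space:]]+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad))
      stop("malformed XYZ atom record at line ", i + 1L + bad[1], ": ", path,
           call. = FALSE)
    el <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(t)
      suppressWarnings(as.numeric(t[2:4])), numeric(3)))
    if (anyNA(xyz))
      stop("non-numeric coordinate in XYZ block starting at line ", i, ": ",
           path, call. = FALSE)
    blocks[[length(blocks) + 1L]] <- list(elements = el, coords = xyz,
                                          comment = comment)
    i <- i + 2L + n
  }
  blocks
}

formatXyzBlock <- function(elements, coords, comment = "") {
  c(as.character(length(elements)), comment,
    sprintf("%-2s %.17g %.17g %.17g", elements,
            coords[, 1], coords[, 2], coords[, 3]))
}

#' Write a molecular structure to XYZ or SDF (V2000)
#'
#' The SDF writer emits a coordinate-only V2000 block (no bond block), which
#' is sufficient for the coordinate-driven representations used here.
#'
#' @param mol a [Molecule3D-class]
#' @param path output path
#' @param format `"xyz"` or `"sdf"`
#' @export
writeStructure <- function(mol, path, format = c("xyz", "sdf")) {
  format <- match.arg(format)
  if (format == "xyz") {
    writeLines(formatXyzBlock(mol@elements, mol@coords, "chirsep molecule"), path)
  } else {
    n <- nAtoms(mol)
    header <- c("chirsep molecule", "  chirsep", "",
                sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L))
    atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     mol@coords[, 1], mol@coords[, 2], mol@coords[, 3],
                     mol@elements)
    writeLines(c(header, atoms, "M  END", "$$$$"), path)
  }
  invisible(path)
}

#' Read a conformer ensemble (multi-frame XYZ)
#'
#' Frames are returned in storage order. If the file was written by
#' [writeFrames()], the substrate/agent split and handedness are recovered
#' from the comment lines; otherwise a `template` complex must be supplied.
#'
#' @param path multi-frame XYZ file.
#' @param template optional [SaltComplex-class] defining atoms and split.
#' @return a [FrameSet-class]
#' @export
readFrames <- function(path, template = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  blocks <- parseXyzBlocks(readLines(path), path)
  if (length(blocks) < 2L)
    stop("a FrameSet needs at least 2 frames; found ", length(blocks), ": ",
         path, call. = FALSE)
  ns <- vapply(blocks, function(b) length(b$elements), integer(1))
  if (length(unique(ns)) != 1L)
    stop("inconsistent atom count across frames (", paste(unique(ns), collapse = ", "),
         "): ", path, call. = FALSE)
  if (is.null(template)) {
    meta <- regmatches(blocks[[1]]$comment,
                       regexec("chirsep sub=(\\d+) hand=([RS])", blocks[[1]]$comment))[[1]]
    if (length(meta) != 3L)
      stop("no chirsep frame metadata in file; supply a template complex: ",
           path, call. = FALSE)
    nsub <- as.integer(meta[2])
    el <- blocks[[1]]$elements
    co <- blocks[[1]]$coords
    template <- saltComplex(
      molecule3d(el[seq_len(nsub)], co[seq_len(nsub), , drop = FALSE],
                 role = "substrate"),
      molecule3d(el[-seq_len(nsub)], co[-seq_len(nsub), , drop = FALSE],
                 role = "resolving_agent"),
      handedness = meta[3])
  }
  if (ns[1] != nAtoms(template))
    stop("frame atom count ", ns[1], " does not match template (",
         nAtoms(template), "): ", path, call. = FALSE)
  new("FrameSet", complexTemplate = template,
      frames = lapply(blocks, `[[`, "coords"))
}

#' Write a conformer ensemble as multi-frame XYZ
#'
#' Comment lines carry the substrate size and handedness so
#' [readFrames()] can reconstruct the complex without a template. Coordinates
#' are written with 17 significant digits and round-trip bitwise.
#'
#' @param frameSet a [FrameSet-class]
#' @param path output path
#' @export
writeFrames <- function(frameSet, path) {
  tpl <- frameSet@complexTemplate
  el <- elementsOf(tpl)
  nsub <- nAtoms(tpl@substrate)
  lines <- unlist(lapply(seq_along(frameSet@frames), function(i) {
    formatXyzBlock(el, frameSet@frames[[i]],
                   sprintf("chirsep sub=%d hand=%s frame=%d", nsub,
                           tpl@handedness, i))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Load a resolution experiment table
#'
#' Expected CSV columns: `racemate_id`, `agent_id`, `solvent_ids`
#' (semicolon-separated), `solvent_fractions` (semicolon-separated molar
#' fractions), `m_frac`, `ee`, and optionally `full_dissolution`. Records
#' with `m_frac == 0` have `ee` stored as 0 by convention (no solid means
#' the excess is undefined) and are flagged in the `ee_imputed` column.
#'
#' @param path CSV file path.
#' @return data.frame with one row per experiment, fractions stored in the
#'   list column `solvent_fractions`.
#' @export
loadExperimentTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty experiment table: ", path)
    return(df)
  }
  need <- c("racemate_id", "agent_id", "solvent_ids", "solvent_fractions",
            "m_frac", "ee")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  ids <- strsplit(as.character(df$solvent_ids), ";", fixed = TRUE)
  fr <- lapply(strsplit(as.character(df$solvent_fractions), ";", fixed = TRUE),
               as.numeric)
  sums <- vapply(fr, sum, numeric(1))
  bad <- which(abs(sums - 1) > 1e-6 | vapply(fr, function(x) any(!is.finite(x) | x <= 0), logical(1)))
  if (length(bad))
    stop("solvent molar fractions must be positive and sum to 1 (row ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  if (any(df$m_frac < 0 | df$m_frac > 1 | df$ee < 0 | df$ee > 1, na.rm = TRUE))
    stop("m_frac and ee must lie in [0, 1]", call. = FALSE)
  df$solvent_ids <- I(ids)
  df$solvent_fractions <- I(fr)
  df$ee_imputed <- df$m_frac == 0 & df$ee != 0
  df$ee[df$m_frac == 0] <- 0
  if (!"full_dissolution" %in% names(df)) df$full_dissolution <- NA
  df
}

#' Write a resolution experiment table
#' @param df experiment data.frame as produced by [loadExperimentTable()] or
#'   [generateDataset()]
#' @param path output CSV path
#' @export
writeExperimentTable <- function(df, path) {
  out <- df
  out$solvent_ids <- vapply(df$solvent_ids, paste, character(1), collapse = ";")
  out$solvent_fractions <- vapply(df$solvent_fractions, function(x)
    paste(format(x, digits = 10), collapse = ";"), character(1))
  keep <- intersect(c("racemate_id", "agent_id", "solvent_ids",
                      "solvent_fractions", "m_frac", "ee", "full_dissolution"),
                    names(out))
  utils::write.csv(out[keep], path, row.names = FALSE)
  invisible(path)
}

#' Maximum attainable enantiomeric excess for a given solid mass fraction
#'
#' Assuming a racemic (50:50) feed: if less than half of the substrate
#' crystallises the solid can be enantiopure (max e.e. = 1); beyond that the
#' minority enantiomer must start to co-crystallise and the bound is
#' (1 - m_frac) / m_frac.
#'
#' @param m_frac solid mass fraction(s) in \[0, 1\]
#' @return numeric vector of maximum e.e. values
#' @export
maxPossibleEe <- function(m_frac) {
  ifelse(m_frac <= 0.5, 1, (1 - m_frac) / m_frac)
}

#' Keep/discard decision for experiment records
#'
#' A record is physically consistent if its e.e. does not exceed the maximum
#' possible e.e. for its mass fraction by more than a 0.05 experimental-error
#' band; inconsistent records are discarded.
#'
#' @param m_frac,ee numeric vectors of equal length
#' @return data.frame with columns `keep` (logical), `max_ee`, `reason`
#' @export
validateRecord <- function(m_frac, ee) {
  stopifnot(length(m_frac) == length(ee))
  max_ee <- maxPossibleEe(m_frac)
  keep <- ee <= max_ee + 0.05
  data.frame(keep = keep, max_ee = max_ee,
             reason = ifelse(keep, "ok", "ee exceeds maximum possible ee + 0.05"),
             stringsAsFactors = FALSE)
}

#' Apply the physical-consistency filter to an experiment table
#'
#' @param df experiment data.frame
#' @return the kept subset; kept/discarded counts are reported via `message()`
#' @export
filterExperiments <- function(df) {
  v <- validateRecord(df$m_frac, df$ee)
  message(sprintf("experiment filter: kept %d of %d records (%d discarded)",
                  sum(v$keep), nrow(df), sum(!v$keep)))
  df[v$keep, , drop = FALSE]
}

#' Load a solvent descriptor table
#'
#' One row per solvent id; all remaining columns form the fixed-length
#' descriptor schema (physical properties plus surface-charge-profile bins).
#'
#' @param path CSV file path
#' @return data.frame with rownames = solvent ids, numeric columns
#' @export
loadSolventTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"solvent_id" %in% names(df)) stop("missing 'solvent_id' column", call. = FALSE)
  m <- as.data.frame(df[setdiff(names(df), "solvent_id")])
  if (!all(vapply(m, is.numeric, logical(1))))
    stop("solvent descriptor columns must be numeric", call. = FALSE)
  if (any(!is.finite(as.matrix(m)))) stop("solvent descriptors must be finite", call. = FALSE)
  rownames(m) <- df$solvent_id
  m
}
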