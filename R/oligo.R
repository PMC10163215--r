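#' Oligonucleotide probe/target descriptions
#'
#' An `oligo` bundles one synthetic strand of the genotyping panel with its
#' metadata. Probes are written 5'->3' and carry a thiol-C6 linker at the 5'
#' end (metadata only -- the linker does not base-pair); targets are stored
#' 3'->5' exactly as designed so that a position-wise comparison against the
#' probe string needs no index reversal. The character `-` marks an
#' explicitly unpaired position (insertion/deletion placeholder) so that
#' cross-pairings of mutation and wild-type strands line up without any
#' alignment algorithm.
#'
#' @param id Character scalar, unique identifier (e.g. `"probe_DNA_4"`).
#' @param sequence Character scalar over the alphabet `A,C,G,T,-`.
#' @param role `"probe"` or `"target"`.
#' @param orientation `"5to3"` (probes) or `"3to5"` (targets).
#' @param thiol_modified Logical; `TRUE` for surface-immobilised probes.
#' @param variant_label Mutation panel the strand belongs to
#'   (e.g. `"5382insC"`).
#' @param mutation_bearing Logical; does the strand carry the variant?
#'
#' @return An object of class `oligo`.
#' @export
oligo <- function(id, sequence, role = c("probe", "target"),
                  orientation = c("5to3", "3to5"),
                  thiol_modified = FALSE, variant_label = "",
                  mutation_bearing = FALSE) {
  role <- match.arg(role)
  orientation <- match.arg(orientation)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence))
    stop("oligo '", id, "': sequence must be non-empty", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "-"))
  if (length(bad))
    stop("oligo '", id, "': invalid characters in sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (isTRUE(thiol_modified) && chars[1L] == "-")
    stop("oligo '", id, "': a gap placeholder cannot occupy the thiol ",
         "linker position", call. = FALSE)
  structure(
    list(id = id, sequence = sequence, role = role,
         orientation = orientation, thiol_modified = isTRUE(thiol_modified),
         variant_label = variant_label,
         mutation_bearing = isTRUE(mutation_bearing)),
    class = "oligo")
}

#' @export
print.oligo <- function(x, ...) {
  cat(sprintf("<oligo> %s [%s, %s%s] %s\n  %s (%d nt incl. gaps)\n",
              x$id, x$role, x$variant_label,
              if (x$mutation_bearing) ", mutant" else "",
              if (x$thiol_modified) "thiol-C6" else "",
              x$sequence, nchar(x$sequence)))
  invisible(x)
}

# Watson-Crick complement lookup used throughout the module.
.wc_complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Position-wise duplex pairing of a probe and a target strand
#'
#' Scans two equal-length padded strands (probe 5'->3' against target 3'->5')
#' position by position and records for each position whether it is a
#' Watson-Crick match (A:T, C:G), a mismatch, a gap placeholder facing a base
#' (an unpaired bulge/loop base), or a gap facing a gap (a position deleted
#' from both strands of the panel design).
#'
#' @param probe,target `oligo` objects with matching padded lengths.
#' @return An object of class `duplex_alignment` with fields `probe_id`,
#'   `target_id`, `pair_states` (character vector over positions),
#'   `n_match`, `n_mismatch`, `n_gap` (gaps of either kind),
#'   `n_gap_opposite_base`, and `fully_complementary`.
#' @export
#' @examples
#' p <- oligo("p", "ACGT", "probe", "5to3")
#' t <- oligo("t", "TGCA", "target", "3to5")
#' pair_positions(p, t)$fully_complementary
pair_positions <- function(probe, target) {
  stopifnot(inherits(probe, "oligo"), inherits(target, "oligo"))
  if (probe$role != "probe" || target$role != "target")
    stop("pair_positions() expects a probe and a target, got roles '",
         probe$role, "' and '", target$role, "'", call. = FALSE)
  p <- strsplit(probe$sequence, "", fixed = TRUE)[[1L]]
  t <- strsplit(target$sequence, "", fixed = TRUE)[[1L]]
  if (length(p) != length(t))
    stop("padded lengths differ: ", probe$id, " has ", length(p),
         " positions, ", target$id, " has ", length(t), call. = FALSE)
  state <- character(length(p))
  pg <- p == "-"; tg <- t == "-"
  state[pg & tg] <- "gap_opposite_gap"
  state[xor(pg, tg)] <- "gap_opposite_base"
  both <- !pg & !tg
  state[both] <- ifelse(.wc_complement[p[both]] == t[both],
                        "watson_crick_match", "mismatch")
  n_match <- sum(state == "watson_crick_match")
  n_mismatch <- sum(state == "mismatch")
  n_gob <- sum(state == "gap_opposite_base")
  n_gap <- n_gob + sum(state == "gap_opposite_gap")
  structure(
    list(probe_id = probe$id, target_id = target$id, pair_states = state,
         n_match = n_match, n_mismatch = n_mismatch, n_gap = n_gap,
         n_gap_opposite_base = n_gob,
         fully_complementary = n_mismatch == 0L && n_gob == 0L),
    class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf(
    "<duplex_alignment> %s vs %s: %d match, %d mismatch, %d gap (%d vs base)%s\n",
    x$probe_id, x$target_id, x$n_match, x$n_mismatch, x$n_gap,
    x$n_gap_opposite_base,
    if (x$fully_complementary) " [fully complementary]" else ""))
  invisible(x)
}

#' Classify a duplex alignment into the kinetic-regime classes
#'
#' Maps the position-wise defect counts onto the duplex classes whose binding
#' kinetics the assay contrasts: a fully complementary duplex, a single
#' internal mismatch (point mutation), a bulge or loop (one strand carries
#' unpaired bases), or multiple defects.
#'
#' @param alignment A `duplex_alignment`.
#' @return One of `"full_complement"`, `"point_mismatch"`,
#'   `"bulge_or_loop"`, `"multi_defect"`.
#' @export
classify_duplex <- function(alignment) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  if (alignment$fully_complementary) return("full_complement")
  if (alignment$n_mismatch == 1L && alignment$n_gap_opposite_base == 0L)
    return("point_mismatch")
  if (alignment$n_mismatch == 0L && alignment$n_gap_opposite_base >= 1L)
    return("bulge_or_loop")
  "multi_defect"
}

#' Read a panel of oligos from a FASTA-like fixture
#'
#' The description line carries `key=value` metadata
#' (`role`, `orientation`, `variant`, `mutation_bearing`, `thiol`); gap
#' placeholders `-` are allowed in sequence lines.
#'
#' @param path Path to the FASTA file.
#' @return Named list of `oligo` objects (names are the record ids).
#' @export
read_oligo_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  out <- vector("list", length(set))
  ids <- character(length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    toks <- strsplit(header, "\\s+")[[1L]]
    id <- toks[1L]
    kv <- toks[-1L][grepl("=", toks[-1L], fixed = TRUE)]
    meta <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    out[[i]] <- oligo(
      id = id,
      sequence = as.character(set[[i]]),
      role = meta[["role"]],
      orientation = meta[["orientation"]],
      thiol_modified = identical(meta[["thiol"]], "TRUE"),
      variant_label = meta[["variant"]],
      mutation_bearing = identical(meta[["mutation_bearing"]], "TRUE"))
    ids[i] <- id
  }
  stats::setNames(out, ids)
}

#' The packaged oligonucleotide panel
#'
#' Loads the ten probe/target pairs (five mutation panels, with and without
#' the variant) shipped with the package.
#'
#' @return Named list of `oligo` objects.
#' @export
panel_oligos <- function() {
  read_oligo_fasta(system.file("extdata", "table1_oligos.fasta",
                               package = "genosensr", mustWork = TRUE))
}
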