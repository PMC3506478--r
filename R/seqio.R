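## Alignment containers, FASTA/Newick I/O, trimming and reference maps.
##
## Coordinates are 1-based and closed-interval throughout.  Trimming the
## leading part of an alignment retains an origin offset so downstream
## site numbers always refer to the untrimmed reference numbering.

.msa_symbols <- list(
  protein = c(AMINO_ACIDS, "-", "X"),
  nucleotide = c(NUCLEOTIDES, "-", "N")
)

#' Construct a multiple alignment
#'
#' @param ids unique sequence identifiers (input order preserved).
#' @param seqs character vector of aligned rows (equal lengths).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param offset number of leading residues/basepairs trimmed from the
#'   original alignment (0 for untrimmed data); used so reported site
#'   numbers refer to original coordinates.
#' @return object of class `msa`: a character matrix (sequences x
#'   columns) with attributes `alphabet` and `offset`.
#' @export
msa <- function(ids, seqs, alphabet = c("protein", "nucleotide"),
                offset = 0L) {
  alphabet <- match.arg(alphabet)
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1)
    stop("unequal row lengths: ",
         paste(ids[lens != lens[1]], collapse = ", "))
  m <- do.call(rbind, strsplit(seqs, ""))
  if (is.null(m)) m <- matrix(character(0), 0, 0)
  rownames(m) <- ids
  ok <- m %in% .msa_symbols[[alphabet]]
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow(m)), arr.ind = TRUE)[1, ]
    stop(sprintf("illegal %s symbol '%s' in sequence '%s' at column %d",
                 alphabet, m[bad[1], bad[2]], ids[bad[1]], bad[2]))
  }
  structure(m, alphabet = alphabet, offset = as.integer(offset),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequences x %d columns (%s%s)\n",
              nrow(x), ncol(x), attr(x, "alphabet"),
              if (attr(x, "offset") > 0)
                sprintf(", offset %d", attr(x, "offset")) else ""))
  invisible(x)
}

n_columns <- function(aln) ncol(aln)

msa_ids <- function(aln) rownames(aln)

msa_strings <- function(aln) apply(unclass(aln), 1, paste, collapse = "")

#' Read a FASTA alignment
#'
#' @param path FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return an [msa()] in file order.
#' @export
read_alignment <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)          # first token only
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")),
                 character(1))
  if (length(seqs) != length(ids)) stop("FASTA record without sequence")
  msa(ids, unname(seqs), alphabet)
}

#' Write a FASTA alignment
#'
#' @param aln an [msa()] or [as_codon_alignment()] result.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_alignment <- function(aln, path, width = 70) {
  if (inherits(aln, "codon_msa")) aln <- aln$base
  con <- file(path, "w")
  on.exit(close(con))
  s <- msa_strings(aln)
  for (i in seq_along(s)) {
    writeLines(paste0(">", names(s)[i]), con)
    writeLines(substring(s[i], seq(1, nchar(s[i]), width),
                         pmin(nchar(s[i]), seq(1, nchar(s[i]), width) + width - 1)),
               con)
  }
  invisible(path)
}

#' View a nucleotide alignment as an in-frame codon alignment
#'
#' Validates frame (length divisible by 3), whole-codon gaps, and the
#' absence of internal stop codons (a stop at the final codon position
#' is allowed and masked as missing).
#'
#' @param aln nucleotide [msa()].
#' @return object of class `codon_msa`: list with elements `base` (the
#'   nucleotide msa), `n_codon_sites`, `codons` (sequences x sites codon
#'   string matrix) and `offset_codons`.
#' @export
as_codon_alignment <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  if (attr(aln, "alphabet") != "nucleotide")
    stop("codon view requires a nucleotide alignment")
  L <- ncol(aln)
  if (L %% 3 != 0) stop("alignment length ", L, " not divisible by 3")
  off <- attr(aln, "offset")
  if (off %% 3 != 0) stop("trim offset not divisible by 3")
  ns <- L / 3
  ids <- msa_ids(aln)
  codons <- matrix("", nrow(aln), ns, dimnames = list(ids, NULL))
  for (s in seq_len(ns)) {
    codons[, s] <- paste0(aln[, 3 * s - 2], aln[, 3 * s - 1], aln[, 3 * s])
  }
  has_gap <- matrix(grepl("-", codons), nrow(aln))
  all_gap <- codons == "---"
  if (any(has_gap & !all_gap)) {
    bad <- which(has_gap & !all_gap, arr.ind = TRUE)[1, ]
    stop(sprintf("partial-codon gap in sequence '%s' at codon %d",
                 ids[bad[1]], bad[2]))
  }
  is_stop <- matrix(codons %in% STOP_CODONS, nrow(aln))
  if (ns > 1 && any(is_stop[, -ns, drop = FALSE])) {
    bad <- which(is_stop[, -ns, drop = FALSE], arr.ind = TRUE)[1, ]
    stop(sprintf("internal stop codon in sequence '%s' at codon %d",
                 ids[bad[1]], bad[2]))
  }
  if (any(is_stop[, ns])) codons[is_stop[, ns], ns] <- "NNN"
  structure(list(base = aln, n_codon_sites = ns, codons = codons,
                 offset_codons = off %/% 3L),
            class = "codon_msa")
}

#' @export
print.codon_msa <- function(x, ...) {
  cat(sprintf("Codon alignment: %d sequences x %d codon sites%s\n",
              nrow(x$codons), x$n_codon_sites,
              if (x$offset_codons > 0)
                sprintf(" (offset %d codons)", x$offset_codons) else ""))
  invisible(x)
}

#' Remove leading alignment columns, keeping original numbering
#'
#' Drops the first `n_units` residues (protein) or basepairs (codon
#' alignments; must be a multiple of 3) and records them in the `offset`
#' attribute so downstream coordinates refer to the untrimmed alignment.
#'
#' @param aln an [msa()] or `codon_msa`.
#' @param n_units leading units to drop.
#' @return trimmed alignment of the same class.
#' @export
trim_leading <- function(aln, n_units) {
  n_units <- as.integer(n_units)
  if (n_units < 0) stop("n_units must be >= 0")
  if (inherits(aln, "codon_msa")) {
    if (n_units %% 3 != 0)
      stop("n_units must be a multiple of 3 for codon alignments")
    return(as_codon_alignment(trim_leading(aln$base, n_units)))
  }
  stopifnot(inherits(aln, "msa"))
  if (n_units >= ncol(aln))
    stop("n_units (", n_units, ") >= alignment length (", ncol(aln), ")")
  if (n_units == 0) return(aln)
  out <- unclass(aln)[, -(seq_len(n_units)), drop = FALSE]
  structure(out, alphabet = attr(aln, "alphabet"),
            offset = attr(aln, "offset") + n_units, class = "msa")
}

#' Map alignment columns to reference-sequence numbering
#'
#' Numbers the non-gap positions of the chosen reference row 1,2,...
#' (plus any trim offset carried by the alignment) and records the
#' mutually inverse column/residue maps.  For codon alignments the map
#' is over codon sites.
#'
#' @param aln an [msa()] or `codon_msa`.
#' @param reference_id identifier of the reference row.
#' @return object of class `ref_map`: list with `reference_id`,
#'   `column_to_residue` (integer vector over columns, `NA` at reference
#'   gaps) and `residue_to_column` (named integer vector).
#' @export
build_reference_map <- function(aln, reference_id) {
  if (inherits(aln, "codon_msa")) {
    row <- aln$codons[match_ref(aln$codons, reference_id), ]
    nongap <- row != "---"
    off <- aln$offset_codons
  } else {
    row <- unclass(aln)[match_ref(aln, reference_id), ]
    nongap <- row != "-"
    off <- attr(aln, "offset")
  }
  c2r <- rep(NA_integer_, length(row))
  c2r[nongap] <- seq_len(sum(nongap)) + off
  r2c <- which(nongap)
  names(r2c) <- c2r[nongap]
  structure(list(reference_id = reference_id, column_to_residue = c2r,
                 residue_to_column = r2c),
            class = "ref_map")
}

match_ref <- function(x, reference_id) {
  i <- match(reference_id, rownames(x))
  if (is.na(i)) stop("unknown identifier: ", reference_id)
  i
}

#' Read / write Newick trees
#'
#' Thin wrappers around the `ape` Newick parser with validation of leaf
#' label uniqueness.
#' @param path Newick file.
#' @return an `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("invalid Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("invalid Newick file: ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Check that a tree's leaves are all present in an alignment
#'
#' @param tree a `phylo`.
#' @param aln an [msa()] or `codon_msa`.
#' @return invisibly `TRUE`; errors on mismatch.
#' @export
check_tree_alignment <- function(tree, aln) {
  ids <- if (inherits(aln, "codon_msa")) msa_ids(aln$base) else msa_ids(aln)
  missing <- setdiff(tree$tip.label, ids)
  if (length(missing))
    stop("tree leaves absent from alignment: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
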