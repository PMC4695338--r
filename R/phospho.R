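# -- phospho-site bookkeeping and net-charge modelling ---------------------

#' Protein record with named regions
#'
#' @param sequence Amino-acid sequence (single string, 1-based numbering).
#' @param regions Data frame with columns `region`, `start`, `end`
#'   (inclusive residue ranges); regions must be non-overlapping and inside
#'   the sequence.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(sequence, regions = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (!is.null(regions)) {
    stopifnot(all(c("region", "start", "end") %in% names(regions)))
    if (any(regions$start < 1 | regions$end > n |
            regions$start > regions$end))
      stop_param("region ranges must lie within the sequence")
    o <- order(regions$start)
    if (any(regions$start[o][-1] <= regions$end[o][-nrow(regions)]))
      stop_param("regions must not overlap")
  }
  structure(list(sequence = sequence, regions = regions),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("protein_record:", nchar(x$sequence), "aa")
  if (!is.null(x$regions))
    cat(";", nrow(x$regions), "regions:",
        paste(x$regions$region, collapse = ", "))
  cat("\n")
  invisible(x)
}

residues_at <- function(protein, positions) {
  vapply(positions, function(p) substr(protein$sequence, p, p), character(1))
}

#' Phosphorylation site set
#'
#' @param protein The `protein_record` the positions refer to.
#' @param positions Integer residue positions.
#' @param provenance Character label(s) recording which study detected each
#'   site.
#' @return A `phospho_sites` data frame (`position`, `residue`,
#'   `provenance`), validated so every site is an S/T/Y residue matching
#'   the sequence.
#' @export
phospho_sites <- function(protein, positions, provenance = "unspecified") {
  stopifnot(inherits(protein, "protein_record"))
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) stop_param("duplicate site positions")
  if (any(positions < 1 | positions > nchar(protein$sequence)))
    stop_param("site positions outside the sequence")
  res <- residues_at(protein, positions)
  bad <- !res %in% c("S", "T", "Y")
  if (any(bad))
    stop_param("position(s) ", paste(positions[bad], collapse = ", "),
               " are not Ser/Thr/Tyr residues")
  out <- data.frame(position = positions, residue = res,
                    provenance = provenance, stringsAsFactors = FALSE)
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  structure(out, class = c("phospho_sites", "data.frame"))
}

#' Merge two phospho-site sets by set union
#'
#' Provenance labels of sites found in both sets are concatenated; a shared
#' position with conflicting residue letters is a hard error. The union
#' cardinality obeys inclusion-exclusion: `|a| + |b| - |a intersect b|`.
#'
#' @param a,b `phospho_sites` validated against the same sequence.
#' @return A merged `phospho_sites`.
#' @export
merge_site_sets <- function(a, b) {
  stopifnot(inherits(a, "phospho_sites"), inherits(b, "phospho_sites"))
  shared <- intersect(a$position, b$position)
  if (length(shared)) {
    ra <- a$residue[match(shared, a$position)]
    rb <- b$residue[match(shared, b$position)]
    if (any(ra != rb))
      stop_param("conflicting residue letters at shared position(s): ",
                 paste(shared[ra != rb], collapse = ", "))
  }
  only_b <- b[!b$position %in% shared, , drop = FALSE]
  out <- rbind(as.data.frame(a), as.data.frame(only_b))
  i <- match(shared, out$position)
  out$provenance[i] <- paste(a$provenance[match(shared, a$position)],
                             b$provenance[match(shared, b$position)],
                             sep = "+")
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  structure(out, class = c("phospho_sites", "data.frame"))
}

#' Mutation specification (ordered substitutions and insertions)
#'
#' @param name Mutant name (e.g. `"MIM22"`).
#' @param substitutions Data frame with `position`, `from`, `to` (single
#'   residues, positions on the pre-edit sequence).
#' @param insertions Data frame with `after` (position after which to
#'   insert, pre-edit coordinates; 0 prepends) and `residues` (string).
#' @return A `mutant_spec`.
#' @export
mutant_spec <- function(name, substitutions = NULL, insertions = NULL) {
  if (!is.null(substitutions)) {
    stopifnot(all(c("position", "from", "to") %in% names(substitutions)))
    if (anyDuplicated(substitutions$position))
      stop_param("duplicate substitution positions")
  }
  if (!is.null(insertions))
    stopifnot(all(c("after", "residues") %in% names(insertions)))
  structure(list(name = name, substitutions = substitutions,
                 insertions = insertions), class = "mutant_spec")
}

#' @export
print.mutant_spec <- function(x, ...) {
  ns <- if (is.null(x$substitutions)) 0L else nrow(x$substitutions)
  ni <- if (is.null(x$insertions)) 0L else
    sum(nchar(x$insertions$residues))
  cat(sprintf("mutant_spec %s: %d substitution(s), %d inserted residue(s)\n",
              x$name, ns, ni))
  invisible(x)
}

#' Apply a mutation specification to a protein
#'
#' Substitutions are checked against the pre-edit sequence (a mismatching
#' `from` residue is a hard error naming the position); insertions are then
#' applied in ascending position order, and region ranges are shifted (or
#' extended, for insertions falling inside a region) consistently.
#'
#' @param protein A `protein_record`.
#' @param spec A `mutant_spec`.
#' @return The edited `protein_record`.
#' @export
apply_mutations <- function(protein, spec) {
  stopifnot(inherits(protein, "protein_record"),
            inherits(spec, "mutant_spec"))
  seq <- strsplit(protein$sequence, "")[[1]]
  subs <- spec$substitutions
  if (!is.null(subs) && nrow(subs)) {
    if (any(subs$position < 1 | subs$position > length(seq)))
      stop_param("substitution position outside the sequence")
    have <- seq[subs$position]
    bad <- have != subs$from
    if (any(bad))
      stop_param("substitution 'from' mismatch at position(s) ",
                 paste(subs$position[bad], collapse = ", "),
                 " (sequence has ",
                 paste(have[bad], collapse = ", "), ")")
    seq[subs$position] <- subs$to
  }
  regions <- protein$regions
  ins <- spec$insertions
  if (!is.null(ins) && nrow(ins)) {
    ins <- ins[order(ins$after), , drop = FALSE]
    offset <- 0L
    for (k in seq_len(nrow(ins))) {
      p <- ins$after[k] + offset
      if (p < 0 || p > length(seq))
        stop_param("insertion point outside the sequence")
      res <- strsplit(toupper(ins$residues[k]), "")[[1]]
      seq <- append(seq, res, after = p)
      if (!is.null(regions)) {
        m <- length(res)
        shift_all <- regions$start > p
        inside <- regions$start <= p & regions$end > p
        regions$start[shift_all] <- regions$start[shift_all] + m
        regions$end[shift_all | inside] <- regions$end[shift_all | inside] + m
      }
      offset <- offset + length(res)
    }
  }
  protein_record(paste(seq, collapse = ""), regions)
}

#' Default residue charge table at neutral pH
#'
#' Asp/Glu -1, Lys/Arg +1, His 0, everything else 0; the charge of a
#' phosphorylated Ser/Thr is handled separately (default -2 per site).
#'
#' @return Named numeric vector over the 20 amino-acid letters.
#' @export
default_charge_table <- function() {
  tab <- stats::setNames(rep(0, 20),
                         strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  tab[c("D", "E")] <- -1
  tab[c("K", "R")] <- +1
  tab
}

#' Net charge of a protein region under a stated charge model
#'
#' Computes `q = sum` of per-residue charges over one or more named regions
#' (or the whole chain), optionally treating a set of phospho-sites as
#' carrying the phosphate charge instead of their base charge. This is the
#' quantity behind the electrostatic argument for HP1-like hinge-RNA
#' binding: phosphorylation (or phospho-mimic Glu) drives the region more
#' negative, Lys insertions/substitutions drive it back up.
#'
#' @param protein A `protein_record`.
#' @param regions Character vector of region names (default: all named
#'   regions; if the protein has none, the whole sequence).
#' @param phospho Optional `phospho_sites`; sites inside the selected
#'   regions contribute `phospho_charge` instead of their base charge.
#' @param charge_table Named residue-charge vector
#'   (default [default_charge_table()]).
#' @param phospho_charge Charge per phosphorylated residue (default -2 at
#'   neutral pH; -1.5 is a common alternative).
#' @return A `charge_report`: list with `regions`, `charge` and a
#'   per-residue `breakdown` data frame whose charges sum to `charge`.
#' @export
net_charge <- function(protein, regions = NULL, phospho = NULL,
                       charge_table = default_charge_table(),
                       phospho_charge = -2) {
  stopifnot(inherits(protein, "protein_record"))
  if (is.null(regions)) {
    if (!is.null(protein$regions)) regions <- protein$regions$region
  }
  if (is.null(regions)) {
    pos <- seq_len(nchar(protein$sequence))
    region_of <- rep("chain", length(pos))
  } else {
    miss <- setdiff(regions, protein$regions$region)
    if (length(miss))
      stop_param("undefined region(s): ", paste(miss, collapse = ", "))
    rr <- protein$regions[protein$regions$region %in% regions, ]
    pos <- unlist(Map(seq, rr$start, rr$end))
    region_of <- rep(rr$region, rr$end - rr$start + 1)
  }
  res <- residues_at(protein, pos)
  unknown <- !res %in% names(charge_table)
  if (any(unknown))
    stop_param("unknown residue letter(s): ",
               paste(unique(res[unknown]), collapse = ", "))
  q <- unname(charge_table[res])
  is_ph <- rep(FALSE, length(pos))
  if (!is.null(phospho)) {
    is_ph <- pos %in% phospho$position
    q[is_ph] <- phospho_charge
  }
  breakdown <- data.frame(position = pos, residue = res,
                          region = region_of, charge = q,
                          phospho = is_ph, stringsAsFactors = FALSE)
  structure(list(regions = unique(region_of), charge = sum(q),
                 breakdown = breakdown),
            class = "charge_report")
}

#' @export
print.charge_report <- function(x, ...) {
  cat(sprintf("net charge over %s: %+g e\n",
              paste(x$regions, collapse = "+"), x$charge))
  invisible(x)
}

#' Rank mutants by regional net charge
#'
#' Applies each mutation spec, computes the (unphosphorylated) net charge
#' over the given regions, and returns the mutants ordered from least to
#' most negative. For the phospho-mimic series this recovers the strict
#' ordering WT > MIM10 > MIM14 > MIM18 > MIM22, with the two
#' charge-restored MIM22 variants tied at MIM22 + 6.
#'
#' @param protein The parent `protein_record`.
#' @param mutants Named list of `mutant_spec`s (a `WT` row with zero edits
#'   is prepended automatically).
#' @param regions Region names over which to compute charge (default the
#'   unconserved N-terminal and hinge regions NT, HNG1, HNG2).
#' @param charge_table Residue charge table.
#' @return Data frame (`name`, `charge`, `delta_vs_wt`) sorted by
#'   decreasing charge.
#' @export
charge_rank <- function(protein, mutants,
                        regions = c("NT", "HNG1", "HNG2"),
                        charge_table = default_charge_table()) {
  stopifnot(length(mutants) >= 1)
  qs <- vapply(mutants, function(sp) {
    net_charge(apply_mutations(protein, sp), regions,
               charge_table = charge_table)$charge
  }, numeric(1))
  q_wt <- net_charge(protein, regions, charge_table = charge_table)$charge
  out <- data.frame(name = c("WT", names(mutants)),
                    charge = c(q_wt, unname(qs)))
  out$delta_vs_wt <- out$charge - q_wt
  out[order(-out$charge), ]
}

#' Read a protein sequence from FASTA
#' @param path FASTA path (first record used).
#' @param regions Optional region data frame (see [protein_record()]).
#' @return A `protein_record`.
#' @export
read_protein_fasta <- function(path, regions = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  protein_record(as.character(aa[[1]]), regions)
}

#' Read a phospho-site set from TSV
#' @param path TSV with columns `position`, `residue`, `provenance`.
#' @param protein `protein_record` to validate against.
#' @return A `phospho_sites`.
#' @export
read_sites_tsv <- function(path, protein) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ps <- phospho_sites(protein, df$position,
                      if ("provenance" %in% names(df)) df$provenance
                      else "unspecified")
  if ("residue" %in% names(df) &&
      any(df$residue[order(df$position)] != ps$residue))
    stop_param("residue letters in ", path,
               " do not match the protein sequence")
  ps
}
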