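# Sequence records, FASTA I/O, translation and ORF extraction.
#
# Records are plain lists with class "contig" (DNA) or "protein_record" (AA);
# collections are unclassed lists in file order. Coordinates throughout are
# 0-based half-open on the forward strand of the contig.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Create a contig record
#'
#' @param id Identifier (first whitespace-delimited token of a FASTA header).
#' @param seq Uppercase IUPAC DNA text restricted to A/C/G/T/N.
#' @param description Free text after the id on the header line.
#' @return A list of class `"contig"` with fields `id`, `description`, `seq`.
#' @export
contig <- function(id, seq, description = "") {
  seq <- toupper(seq)
  check_alphabet(seq, DNA_ALPHABET, id, "contig")
  structure(list(id = id, description = description, seq = seq),
            class = "contig")
}

#' Create a protein record
#'
#' @param id Identifier.
#' @param aa_seq Uppercase one-letter amino acids (20 standard residues plus X).
#' @param source `"orf"` for deduced proteins, `"external"` otherwise.
#' @param description Free text.
#' @return A list of class `"protein_record"`.
#' @export
protein_record <- function(id, aa_seq, source = "external", description = "") {
  aa_seq <- toupper(aa_seq)
  check_alphabet(aa_seq, c(AA_ALPHABET, "X"), id, "protein")
  structure(list(id = id, description = description, aa_seq = aa_seq,
                 source = source),
            class = "protein_record")
}

# Stops with the record id and 1-based position of the first illegal character.
check_alphabet <- function(seq, alphabet, id, what) {
  if (!nzchar(seq)) stop(sprintf("%s '%s': empty sequence", what, id))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    stop(sprintf("%s '%s': illegal character '%s' at position %d",
                 what, id, chars[bad[1]], bad[1]))
  }
  invisible(TRUE)
}

#' Read a FASTA file
#'
#' Multi-line sequences are concatenated, record order is preserved and ids are
#' the first whitespace-delimited token of each header.
#'
#' @param path File path.
#' @param type `"DNA"` for contigs or `"AA"` for proteins.
#' @return A list of [contig()] or [protein_record()] objects.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- unname(as.character(set))
  lapply(seq_along(set), function(i) {
    if (type == "DNA") contig(ids[i], seqs[i], desc[i])
    else protein_record(ids[i], seqs[i], source = "external",
                        description = desc[i])
  })
}

#' Write records to FASTA
#'
#' @param records Non-empty list of [contig()] or [protein_record()] objects.
#' @param path Output path.
#' @param wrap Line width for the sequence; `0` disables wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60) {
  if (length(records) == 0L) stop("no records to write")
  seqs <- vapply(records, record_seq, "")
  ids <- vapply(records, `[[`, "", "id")
  desc <- vapply(records, function(r) r$description %||% "", "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ifelse(nzchar(desc), paste(ids, desc), ids)
  width <- if (wrap <= 0) max(nchar(seqs)) + 1L else as.integer(wrap)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

record_seq <- function(r) if (inherits(r, "contig")) r$seq else r$aa_seq

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Translate DNA in a given frame
#'
#' Standard genetic code; the trailing partial codon is dropped, stop codons
#' become `*` and any codon containing N becomes `X`.
#'
#' @param dna DNA text (A/C/G/T/N).
#' @param offset Frame offset, 0, 1 or 2.
#' @return Amino-acid text (possibly empty).
#' @export
translate_dna <- function(dna, offset = 0) {
  stopifnot(offset %in% 0:2)
  dna <- toupper(dna)
  n <- nchar(dna) - offset
  n_codons <- n %/% 3L
  if (n_codons <= 0L) return("")
  sub <- substr(dna, offset + 1L, offset + 3L * n_codons)
  aa <- Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "X", no.init.codon = TRUE)
  as.character(aa)
}

#' Reverse complement
#'
#' @param dna DNA text (A/C/G/T/N).
#' @return The reverse complement, same alphabet.
#' @export
reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

# Vectorised frame translation: one Biostrings call per frame for a whole
# character vector of sequences (the per-object S4 overhead would otherwise
# dominate transcriptome-scale scans).
translate_frames <- function(seqs, offset) {
  n_codons <- pmax((nchar(seqs) - offset) %/% 3L, 0L)
  sub <- substr(seqs, offset + 1L, offset + 3L * n_codons)
  out <- character(length(seqs))
  nz <- which(n_codons > 0L)
  if (length(nz)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(sub[nz]),
                                if.fuzzy.codon = "X", no.init.codon = TRUE)
    out[nz] <- as.character(aa)
  }
  out
}

#' Find open reading frames in many contigs at once
#'
#' Batch equivalent of [find_orfs()]; translations are vectorised across
#' contigs, which is much faster for whole-transcriptome screens.
#'
#' @inheritParams find_orfs
#' @param contigs List of [contig()]s.
#' @return A single flat list of ORF records (as in [find_orfs()]).
#' @export
find_orfs_many <- function(contigs, min_aa = 80, longest_per_stop = TRUE) {
  stopifnot(min_aa >= 1)
  seqs <- vapply(contigs, `[[`, "", "seq")
  ids <- vapply(contigs, `[[`, "", "id")
  lens <- nchar(seqs)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seqs else rc
    for (frame in 0:2) {
      aa <- translate_frames(s, frame)
      for (i in seq_along(contigs)) {
        if (lens[i] < 6L || !nzchar(aa[i])) next
        out <- c(out, orfs_in_frame(aa[i], ids[i], strand, frame, lens[i],
                                    min_aa, longest_per_stop))
      }
    }
  }
  out
}

#' Find open reading frames in a contig
#'
#' Scans all six frames for ORFs running from an ATG to the first in-frame stop
#' codon; only ORFs with both an initiation and a termination codon are
#' reported. With `longest_per_stop = TRUE` (default) nested ATGs sharing a
#' stop yield a single ORF (the longest). Coordinates are 0-based half-open on
#' the forward strand and include the terminator codon; `aa_seq` does not
#' include the translated stop.
#'
#' @param ctg A [contig()].
#' @param min_aa Minimum aa length of the reported peptide (default 80).
#' @param longest_per_stop Report only the longest ORF per (frame, stop codon).
#' @return A list of ORF records, each a list with fields `contig_id`,
#'   `strand`, `frame`, `start`, `end`, `aa_seq`, `has_terminator`.
#' @export
find_orfs <- function(ctg, min_aa = 80, longest_per_stop = TRUE) {
  stopifnot(inherits(ctg, "contig"))
  find_orfs_many(list(ctg), min_aa = min_aa,
                 longest_per_stop = longest_per_stop)
}

# ORFs within one translated frame. `aa` is the frame's full translation;
# codon i (1-based) covers strand-local nucleotides frame + 3(i-1) .. +3i.
orfs_in_frame <- function(aa, contig_id, strand, frame, contig_len,
                          min_aa, longest_per_stop) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  stops <- which(chars == "*")
  starts <- which(chars == "M")
  if (!length(stops) || !length(starts)) return(list())
  res <- list()
  prev_stop <- 0L
  for (st in stops) {
    cand <- starts[starts > prev_stop & starts < st]
    if (longest_per_stop && length(cand)) cand <- cand[1L]
    for (m in cand) {
      n_aa <- st - m
      if (n_aa < min_aa) next
      local_start <- frame + 3L * (m - 1L)        # 0-based on this strand
      local_end <- frame + 3L * st                # includes terminator codon
      if (strand == "+") {
        fwd <- c(local_start, local_end)
      } else {
        fwd <- c(contig_len - local_end, contig_len - local_start)
      }
      res[[length(res) + 1L]] <- list(
        contig_id = contig_id, strand = strand, frame = frame,
        start = fwd[1], end = fwd[2],
        aa_seq = paste(chars[m:(st - 1L)], collapse = ""),
        has_terminator = TRUE)
    }
    prev_stop <- st
  }
  res
}

#' Tabulate ORF records
#'
#' @param orfs A list of ORF records from [find_orfs()].
#' @return A data.frame with one row per ORF (`contig_id`, `strand`, `frame`,
#'   `start`, `end`, `length_aa`, `aa_seq`).
#' @export
orf_table <- function(orfs) {
  if (!length(orfs)) {
    return(data.frame(contig_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      length_aa = integer(), aa_seq = character()))
  }
  data.frame(
    contig_id = vapply(orfs, `[[`, "", "contig_id"),
    strand = vapply(orfs, `[[`, "", "strand"),
    frame = vapply(orfs, function(o) as.integer(o$frame), 0L),
    start = vapply(orfs, function(o) as.integer(o$start), 0L),
    end = vapply(orfs, function(o) as.integer(o$end), 0L),
    length_aa = vapply(orfs, function(o) nchar(o$aa_seq), 0L),
    aa_seq = vapply(orfs, `[[`, "", "aa_seq"),
    stringsAsFactors = FALSE)
}
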