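## Reference database: allele naming, exon-based sub-transcript construction,
## FASTA/TSV input and output.

HLA_LOCI <- c("A", "B", "C", "DQA1", "DQB1", "DRB1")
HLA_CLASS1_LOCI <- c("A", "B", "C")
HLA_CLASS2_LOCI <- c("DQA1", "DQB1", "DRB1")

## paper-shaped sub-transcript lengths used for RPKM when exact reconstruction
## of the canonical reference is wanted (class I A/B/C; class II DQA1/DQB1/DRB1)
CANONICAL_SUBTRANSCRIPT_NT <- c(
  A = 694L, B = 694L, C = 694L, DQA1 = 400L, DQB1 = 421L, DRB1 = 421L
)

#' Normalize an HLA locus symbol
#'
#' Accepts both the short class II spellings (`DQA`, `DQB`, `DRB`) and the
#' gene names (`DQA1`, `DQB1`, `DRB1`); class I loci are `A`, `B`, `C`.
#'
#' @param locus character vector of locus symbols.
#' @return character vector of normalized locus names.
#' @export
normalize_locus <- function(locus) {
  map <- c(DQA = "DQA1", DQB = "DQB1", DRB = "DRB1")
  up <- toupper(locus)
  out <- ifelse(up %in% names(map), unname(map[up]), up)
  bad <- !(out %in% HLA_LOCI)
  if (any(bad)) {
    stop("unrecognized HLA locus: ", paste(unique(locus[bad]), collapse = ", "))
  }
  out
}

#' Parse IMGT/HLA-style allele names
#'
#' Splits names of the form `"A*01:01:01"` (colon-separated fields) or the
#' legacy 4-digit form `"DRB1*1501"` into locus, two-digit group and HLA
#' class. Grouping is at two-digit resolution: the group is the locus plus
#' the zero-padded first name field (e.g. `"A*01"`). Trailing letter
#' suffixes (expression annotations such as `N`) are kept in `raw_name` but
#' ignored for grouping.
#'
#' @param raw character vector of allele names.
#' @return a data.frame with columns `raw_name`, `locus`, `group`,
#'   `hla_class`.
#' @examples
#' parse_allele_name(c("A*01:01:01", "DRB1*1501"))
#' @export
parse_allele_name <- function(raw) {
  stopifnot(is.character(raw), length(raw) >= 1L)
  m <- regmatches(raw, regexec("^([A-Za-z0-9]+)\\*([0-9A-Za-z:]+)$", raw))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    stop("cannot parse allele name(s): ", paste(raw[bad], collapse = ", "))
  }
  locus <- normalize_locus(vapply(m, `[`, "", 2L))
  field <- vapply(m, `[`, "", 3L)
  first <- sub(":.*$", "", field)
  first <- sub("[A-Za-z]+$", "", first) # drop expression suffix for grouping
  legacy <- !grepl(":", field) & nchar(first) >= 4L
  first[legacy] <- substr(first[legacy], 1L, 2L)
  if (any(first == "")) {
    stop("allele name has empty group field: ",
         paste(raw[first == ""], collapse = ", "))
  }
  first <- ifelse(nchar(first) == 1L, paste0("0", first), first)
  group <- paste0(locus, "*", first)
  data.frame(
    raw_name = raw, locus = locus, group = group,
    hla_class = ifelse(locus %in% HLA_CLASS1_LOCI, "I", "II"),
    stringsAsFactors = FALSE
  )
}

#' Read an exon annotation table
#'
#' TSV with columns `name`, `exon_index`, `start`, `end`; coordinates are
#' 1-based inclusive on the corresponding FASTA sequence.
#'
#' @param path file path.
#' @return data.frame with the four columns, coerced to the right types.
#' @export
read_exon_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "exon_index", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("exon table must have columns: ", paste(need, collapse = ", "))
  }
  tab$exon_index <- as.integer(tab$exon_index)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab[need]
}

required_exons <- function(hla_class) {
  if (hla_class == "I") c(1L, 2L, 3L, 4L) else c(1L, 2L, 3L)
}

#' Parse an allele FASTA plus exon annotations into allele records
#'
#' Each FASTA entry is cut into its annotated exons. Entries whose name does
#' not parse, whose exon coordinates fall outside the sequence or overlap,
#' or that lack a required exon (class I: exons 1-4; class II: exons 1-3)
#' are collected in a `rejected` data.frame with a reason, rather than
#' failing the whole parse.
#'
#' @param fasta path to a FASTA file (optionally gzip-compressed), or a
#'   character scalar holding FASTA-formatted text.
#' @param exon_table data.frame as from [read_exon_table()].
#' @return list with `records` (list of allele records: `name` row from
#'   [parse_allele_name()], `exons` named list of exon sequences, `sequence`
#'   full entry sequence) and `rejected` (data.frame `name`, `reason`).
#' @export
parse_allele_fasta <- function(fasta, exon_table) {
  seqs <- read_fasta(fasta)
  if (length(seqs) == 0L) stop("FASTA contains no entries")
  et <- split(exon_table, exon_table$name)
  records <- list()
  rejected <- list()
  reject <- function(nm, why) {
    rejected[[length(rejected) + 1L]] <<- data.frame(
      name = nm, reason = why, stringsAsFactors = FALSE)
  }
  for (nm in names(seqs)) {
    name <- tryCatch(parse_allele_name(nm), error = function(e) NULL)
    if (is.null(name)) {
      reject(nm, "unparseable allele name")
      next
    }
    rows <- et[[nm]]
    if (is.null(rows)) {
      reject(nm, "no exon annotation")
      next
    }
    rows <- rows[order(rows$exon_index), , drop = FALSE]
    s <- seqs[[nm]]
    if (any(rows$start < 1L | rows$end > nchar(s) | rows$start > rows$end)) {
      reject(nm, "exon coordinates out of bounds")
      next
    }
    if (nrow(rows) > 1L && any(rows$start[-1L] <= rows$end[-nrow(rows)])) {
      reject(nm, "exon coordinates overlap or are not ascending")
      next
    }
    need <- required_exons(name$hla_class)
    if (!all(need %in% rows$exon_index)) {
      reject(nm, paste0("missing required exon(s): ",
                        paste(setdiff(need, rows$exon_index), collapse = ",")))
      next
    }
    exons <- substring(s, rows$start, rows$end)
    names(exons) <- as.character(rows$exon_index)
    records[[length(records) + 1L]] <- list(
      name = name, exons = as.list(exons), sequence = s)
  }
  rejected <- if (length(rejected)) {
    do.call(rbind, rejected)
  } else {
    data.frame(name = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  list(records = records, rejected = rejected)
}

#' Build the exon-derived sub-transcript of one allele
#'
#' Class I sub-transcripts are exon 1 + exon 2 + exon 3 + the first 75 nt of
#' exon 4; class II sub-transcripts are the last 75 nt of exon 1 + exon 2 +
#' the first 75 nt of exon 3. When a flanking exon is shorter than 75 nt the
#' full available exon is used and the record is flagged `short_flank`
#' (attribute on the returned string).
#'
#' @param record allele record as produced by [parse_allele_fasta()] (needs
#'   `$exons`, a named list of exon sequences).
#' @param hla_class `"I"` or `"II"`; defaults to the record's own class.
#' @return the sub-transcript as a character scalar with attribute
#'   `short_flank` (logical).
#' @export
build_subtranscript <- function(record, hla_class = record$name$hla_class) {
  ex <- record$exons
  flank <- 75L
  need <- required_exons(hla_class)
  if (!all(as.character(need) %in% names(ex))) {
    stop("record lacks required exon(s) for class ", hla_class)
  }
  short <- FALSE
  take_head <- function(s) {
    if (nchar(s) < flank) {
      short <<- TRUE
      s
    } else {
      substr(s, 1L, flank)
    }
  }
  take_tail <- function(s) {
    n <- nchar(s)
    if (n < flank) {
      short <<- TRUE
      s
    } else {
      substr(s, n - flank + 1L, n)
    }
  }
  out <- if (hla_class == "I") {
    paste0(ex[["1"]], ex[["2"]], ex[["3"]], take_head(ex[["4"]]))
  } else {
    paste0(take_tail(ex[["1"]]), ex[["2"]], take_head(ex[["3"]]))
  }
  if (nchar(out) == 0L) stop("empty sub-transcript")
  attr(out, "short_flank") <- short
  out
}

#' Assemble a reference database from allele records
#'
#' Computes every record's sub-transcript and collects names, loci,
#' two-digit groups, classes and lengths into an `hla_refdb` object.
#'
#' @param records list of allele records ([parse_allele_fasta()]).
#' @return an `hla_refdb`: list with parallel vectors `name`, `locus`,
#'   `group`, `hla_class`, `seq`, `length_nt`, `short_flank` and the list
#'   column `exons`.
#' @export
build_reference_db <- function(records) {
  if (length(records) == 0L) stop("no allele records")
  nm <- vapply(records, function(r) r$name$raw_name, "")
  if (anyDuplicated(nm)) {
    stop("duplicate allele names: ", paste(nm[duplicated(nm)], collapse = ", "))
  }
  subs <- lapply(records, build_subtranscript)
  db <- list(
    name = nm,
    locus = vapply(records, function(r) r$name$locus, ""),
    group = vapply(records, function(r) r$name$group, ""),
    hla_class = vapply(records, function(r) r$name$hla_class, ""),
    seq = vapply(subs, as.character, ""),
    length_nt = vapply(subs, nchar, 1L),
    short_flank = vapply(subs, attr, TRUE, "short_flank"),
    exons = lapply(records, `[[`, "exons")
  )
  class(db) <- "hla_refdb"
  db
}

#' One-call reference construction
#'
#' @inheritParams parse_allele_fasta
#' @return list with `db` (an `hla_refdb`) and `rejected` (data.frame).
#' @export
build_reference <- function(fasta, exon_table) {
  p <- parse_allele_fasta(fasta, exon_table)
  if (length(p$records) == 0L) {
    stop("all FASTA entries were rejected; first reason: ",
         if (nrow(p$rejected)) p$rejected$reason[1] else "none")
  }
  list(db = build_reference_db(p$records), rejected = p$rejected)
}

#' @export
print.hla_refdb <- function(x, ...) {
  cat("HLA reference database:", length(x$name), "alleles\n")
  tab <- table(x$locus)
  for (l in names(tab)) {
    cat(sprintf("  %-5s %4d alleles, %3d groups, %s nt\n", l, tab[[l]],
                length(unique(x$group[x$locus == l])),
                paste(unique(range(x$length_nt[x$locus == l])),
                      collapse = "-")))
  }
  invisible(x)
}

#' @export
length.hla_refdb <- function(x) length(x$name)

#' Subset a reference database
#'
#' @param x an `hla_refdb`.
#' @param i indices (logical, integer or allele names).
#' @param ... unused.
#' @export
`[.hla_refdb` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$name)
  out <- list(
    name = x$name[i], locus = x$locus[i], group = x$group[i],
    hla_class = x$hla_class[i], seq = x$seq[i], length_nt = x$length_nt[i],
    short_flank = x$short_flank[i], exons = x$exons[i]
  )
  class(out) <- "hla_refdb"
  out
}

#' Write the sub-transcript reference FASTA
#'
#' One entry per allele, header = raw allele name, input order preserved.
#'
#' @param db an `hla_refdb`.
#' @param path output FASTA path.
#' @export
write_reference <- function(db, path) {
  stopifnot(inherits(db, "hla_refdb"))
  if (length(db) == 0L) stop("empty reference database")
  x <- Biostrings::DNAStringSet(db$seq)
  names(x) <- db$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write the reference manifest TSV
#'
#' Columns `name`, `locus`, `group`, `class`, `length_nt`.
#'
#' @param db an `hla_refdb`.
#' @param path output TSV path.
#' @export
write_manifest <- function(db, path) {
  stopifnot(inherits(db, "hla_refdb"))
  utils::write.table(
    data.frame(name = db$name, locus = db$locus, group = db$group,
               class = db$hla_class, length_nt = db$length_nt,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a pre-built sub-transcript reference
#'
#' Rebuilds an `hla_refdb` from a sub-transcript FASTA (exon structure is
#' not recoverable and is left empty; typing and expression do not need it).
#'
#' @param fasta sub-transcript FASTA, as written by [write_reference()].
#' @return an `hla_refdb`.
#' @export
read_reference <- function(fasta) {
  seqs <- read_fasta(fasta)
  name <- parse_allele_name(names(seqs))
  db <- list(
    name = name$raw_name, locus = name$locus, group = name$group,
    hla_class = name$hla_class, seq = unname(unlist(seqs)),
    length_nt = nchar(unname(unlist(seqs))),
    short_flank = rep(NA, length(seqs)),
    exons = rep(list(NULL), length(seqs))
  )
  class(db) <- "hla_refdb"
  db
}

## internal: FASTA reader accepting a path or raw FASTA text
read_fasta <- function(fasta) {
  if (length(fasta) == 1L && !file.exists(fasta) && grepl("^>", fasta)) {
    tf <- tempfile(fileext = ".fa")
    on.exit(unlink(tf))
    writeLines(fasta, tf)
    fasta <- tf
  }
  x <- Biostrings::readDNAStringSet(fasta)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x)) # header word only
  out
}
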