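#' Germline V/D/J segment database
#'
#' A germline database is a data.frame with one row per segment and columns
#' `name`, `segment_type` (`"V"`, `"D"` or `"J"`), `sequence_nt`, `anchor`
#' (0-based nucleotide offset of the conserved Cys codon for V segments, of
#' the conserved Phe/Trp codon for J segments, `NA` for D), and
#' `junction_template_nt`: for a V segment the suffix of `sequence_nt` from
#' the Cys codon to the 3' end, for a J segment the prefix of `sequence_nt`
#' through the end of the Phe/Trp codon, and for a D segment the full coding
#' sequence. The template is the part of the segment that can appear inside
#' an IMGT junction (conserved Cys through conserved Phe/Trp, inclusive).
#'
#' @name germline_db
NULL

.valid_nt <- function(x) grepl("^[ACGT]+$", x)

#' Read a germline segment FASTA
#'
#' Headers must follow `>NAME|V|cys=<offset>`, `>NAME|J|anchor=<offset>` or
#' `>NAME|D`, with 0-based nucleotide offsets of the conserved Cys (V) or
#' Phe/Trp (J) codon within the sequence.
#'
#' @param path Path to a FASTA file.
#' @return A germline database data.frame (see [germline_db]).
#' @export
read_germline_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L) stop("no FASTA records in ", path)
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  recs <- lapply(seq_along(hdr_idx), function(i) {
    header <- sub("^>", "", lines[hdr_idx[i]])
    seq <- toupper(paste0(lines[(hdr_idx[i] + 1L):ends[i]], collapse = ""))
    list(header = header, seq = seq)
  })
  rows <- lapply(recs, function(r) {
    tok <- strsplit(r$header, "|", fixed = TRUE)[[1]]
    if (length(tok) < 2L)
      stop("germline FASTA format error: header lacks segment type: ", r$header)
    name <- trimws(tok[1]); type <- trimws(tok[2])
    if (!type %in% c("V", "D", "J"))
      stop("germline FASTA format error: unknown segment type '", type, "'")
    if (!.valid_nt(r$seq))
      stop("germline FASTA format error: non-ACGT sequence for ", name)
    anchor <- NA_integer_
    if (type == "V") {
      m <- grep("^cys=", tok, value = TRUE)
      if (length(m) == 0L)
        stop("germline FASTA format error: V entry '", name,
             "' lacks cys=<offset> annotation")
      anchor <- as.integer(sub("^cys=", "", m[1]))
    } else if (type == "J") {
      m <- grep("^anchor=", tok, value = TRUE)
      if (length(m) == 0L)
        stop("germline FASTA format error: J entry '", name,
             "' lacks anchor=<offset> annotation")
      anchor <- as.integer(sub("^anchor=", "", m[1]))
    }
    tmpl <- switch(type,
      V = substr(r$seq, anchor + 1L, nchar(r$seq)),
      J = substr(r$seq, 1L, anchor + 3L),
      D = r$seq)
    data.frame(name = name, segment_type = type, sequence_nt = r$seq,
               anchor = anchor, junction_template_nt = tmpl,
               stringsAsFactors = FALSE)
  })
  db <- do.call(rbind, rows)
  bad <- db$segment_type == "V" & substr(db$junction_template_nt, 1, 3) != "TGT"
  if (any(bad))
    warning("V entries whose Cys anchor is not a TGT codon: ",
            paste(db$name[bad], collapse = ", "))
  db
}

#' Write a germline database to FASTA
#'
#' @param db A germline database data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(db, path) {
  hdr <- with(db, ifelse(segment_type == "V", paste0(name, "|V|cys=", anchor),
              ifelse(segment_type == "J", paste0(name, "|J|anchor=", anchor),
                     paste0(name, "|D"))))
  writeLines(as.vector(rbind(paste0(">", hdr), db$sequence_nt)), path)
  invisible(path)
}

#' Bundled synthetic germline fixture
#'
#' Builds the package's synthetic germline segment set for the human TRD and
#' TRG loci. Segment names follow locus nomenclature but the sequences are
#' synthetic: junction-proximal sequences were designed so that the canonical
#' fetal public CDR3 sequences (see [public_clonotype_table()]) are
#' germline-convergent, i.e. can be recombined with at most one non-templated
#' nucleotide. TRGJP is longer than every other TRGJ segment, mirroring the
#' real locus.
#'
#' @return A germline database data.frame (see [germline_db]).
#' @export
synthetic_germline <- function() {
  pad <- function(s) paste0(s)  # V pads: fixed upstream context per segment
  v <- list(
    TRDV1           = c("GACAAAGTAACTCAGAGTCAGCCG", "TGTGCTCTTGGGGAA"),
    TRDV2           = c("GCCATTTACTCAAGTGGTGCAGAT", "TGTGCCTGTGACACC"),
    TRDV3           = c("GTTGGAATGACGATTCAGCCTAAA", "TGTGCCTTTAGGACC"),
    `TRAV38-2DV8`   = c("GCCCAGACAGTCACTCAGTCTCAA", "TGTGCTTATAGGAGC"),
    TRGV8           = c("CTTCAGGAACTCCAGAAGGGTCAA", "TGTGCCACCTGGGAC"),
    TRGV9           = c("GGGGAACTCACCTCTAACGGTCGT", "TGTGCCTTGTGGGAG"),
    TRGV2           = c("GATTCCGTGACTCAATTGGACGGT", "TGTGCCACGTGGGCT"))
  d <- c(TRDD1 = "TACTGGGGAAGTAGT",
         TRDD2 = "TCCTGGGGGATACC",
         TRDD3 = "ACTGGGGGATACAGC")
  j <- c(TRDJ1  = "ACCGATAAACTCATCTTT",
         TRDJ2  = "CTCTGGGACACCACCCGACAGATGTTTTTC",
         TRDJ3  = "ACTTGGGACACCCGACAGATGTTTTTC",
         TRGJP  = "GTTCAAGAGTTGGGCAAAAAAATCAAGGTATTT",
         TRGJP1 = "ACCACTGGTTGGTTCAAGATATTT",
         TRGJ1  = "AATTATTATAAGAAACTCTTT",
         TRGJ2  = "AGTTATTATAAGAAACTCTTT")
  jtrail <- "GGAAAAGGAACC"  # FGKG-style frame region past the anchor
  vrows <- do.call(rbind, lapply(names(v), function(nm) {
    full <- paste0(v[[nm]][1], v[[nm]][2])
    data.frame(name = nm, segment_type = "V", sequence_nt = full,
               anchor = nchar(v[[nm]][1]),
               junction_template_nt = v[[nm]][2], stringsAsFactors = FALSE)
  }))
  drows <- data.frame(name = names(d), segment_type = "D", sequence_nt = unname(d),
                      anchor = NA_integer_, junction_template_nt = unname(d),
                      stringsAsFactors = FALSE)
  jrows <- do.call(rbind, lapply(names(j), function(nm) {
    tmpl <- j[[nm]]
    data.frame(name = nm, segment_type = "J",
               sequence_nt = paste0(tmpl, jtrail),
               anchor = nchar(tmpl) - 3L,
               junction_template_nt = tmpl, stringsAsFactors = FALSE)
  }))
  rbind(vrows, drows, jrows)
}

#' Look up a germline segment, stripping allele suffixes
#'
#' Gene-level lookup: an allele suffix such as `*01` in the query is stripped
#' before matching names in the database.
#'
#' @param db Germline database.
#' @param call Segment name, possibly with allele suffix (e.g. `"TRDV2*01"`).
#' @param segment_type Optional `"V"`, `"D"` or `"J"` restriction.
#' @return A one-row data.frame, or `NULL` when the call cannot be resolved.
#' @export
germline_lookup <- function(db, call, segment_type = NULL) {
  if (is.na(call) || !nzchar(call)) return(NULL)
  gene <- sub("\\*.*$", "", call)
  hit <- db[db$name == gene, , drop = FALSE]
  if (!is.null(segment_type))
    hit <- hit[hit$segment_type == segment_type, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  hit[1, , drop = FALSE]
}
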