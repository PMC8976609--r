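# HGVS cDNA (c.) parsing into representative CDS coordinates.
#
# A coordinate is the pair (base, intron_offset): `base` is the 1-based CDS
# position relative to the translation start; `intron_offset` is the signed
# distance into the flanking intron (0 for exonic positions), so the splice
# acceptor before base 5468 is written "5468-1" and the donor after 7805 is
# "7805+1". Ordering is lexicographic in (base, offset), which matches
# transcript direction.

# regex for one coordinate token, e.g. "5468", "5468-1", "7805+1"
.coord_re <- "(\\d+)([+-]\\d+)?"

#' Parse HGVS cDNA variant descriptions
#'
#' Converts coding-sequence HGVS descriptions (substitutions, deletions,
#' duplications, insertions and deletion-insertions, with optional intronic
#' boundary offsets) into a representative CDS coordinate. The representative
#' position of a multi-base variant is the 5'-most affected base, i.e. the
#' span start, which is the anchor used for binning.
#'
#' The supported grammar is the subset of HGVS needed for coding-exon
#' variants within +/- 20 bp of exon boundaries; anything else (inversions,
#' complex alleles, whole-gene events) is rejected with a parse error rather
#' than mis-parsed. Genomic (`g.`) and protein (`p.`) descriptions raise a
#' wrong-scheme error.
#'
#' @param hgvs_c character vector of HGVS cDNA descriptions, each beginning
#'   with `"c."`.
#' @return A data frame with one row per input: `base` (integer CDS
#'   position), `offset` (signed intronic offset, 0 for exonic) and `label`
#'   (the input string).
#' @examples
#' parse_cdna(c("c.5470_5477delATTGGGCA", "c.5468-1G>A", "c.7805+1G>T"))
#' @export
parse_cdna <- function(hgvs_c) {
  x <- trimws(as.character(hgvs_c))
  bad_scheme <- grepl("^[gpnmr]\\.", x)
  if (any(bad_scheme)) {
    stop_rorscan(
      sprintf(
        "not a cDNA (c.) description: %s",
        paste(unique(x[bad_scheme]), collapse = ", ")
      ),
      "scheme_error"
    )
  }
  no_prefix <- !startsWith(x, "c.")
  if (any(no_prefix)) {
    stop_rorscan(
      sprintf(
        "cannot parse HGVS token (expected 'c.' prefix): %s",
        paste(unique(x[no_prefix]), collapse = ", ")
      ),
      "parse_error"
    )
  }
  body <- gsub("[[:space:]]", "", sub("^c\\.", "", x))
  full <- sprintf("^%s(?:_%s)?(.*)$", .coord_re, .coord_re)
  m <- regmatches(body, regexec(full, body))

  parse_one <- function(parts, label) {
    if (length(parts) == 0 || parts[1] == "") {
      stop_rorscan(sprintf("cannot parse HGVS token: %s", label), "parse_error")
    }
    base <- as.integer(parts[2])
    offset <- if (parts[3] == "") 0L else as.integer(parts[3])
    has_range <- parts[4] != ""
    tail <- parts[6]
    is_sub <- grepl("^[ACGTN]>[ACGTN]$", tail)
    is_indel <- grepl("^(delins[ACGTN]+|delins\\d*|del[ACGTN]*|del\\d*|dup[ACGTN]*|dup\\d*|ins[ACGTN]+|ins\\d+)$", tail)
    ok <- (is_sub && !has_range) || is_indel
    if (!ok || is.na(base) || base < 1L) {
      stop_rorscan(sprintf("cannot parse HGVS token: %s", label), "parse_error")
    }
    if (has_range) {
      end_base <- as.integer(parts[4])
      end_off <- if (parts[5] == "") 0L else as.integer(parts[5])
      if (is.na(end_base) ||
          end_base < base || (end_base == base && end_off < offset)) {
        stop_rorscan(sprintf("cannot parse HGVS token: %s", label), "parse_error")
      }
    }
    c(base = base, offset = offset)
  }

  parsed <- mapply(parse_one, m, x)
  data.frame(
    base = as.integer(parsed["base", ]),
    offset = as.integer(parsed["offset", ]),
    label = x,
    stringsAsFactors = FALSE
  )
}

#' Parse a bare CDS position token
#'
#' Accepts tokens such as `"5468-1"` or `"7805 + 1"` (whitespace ignored) as
#' they appear in bin-boundary tables, without the `"c."` prefix.
#'
#' @param x character vector of position tokens.
#' @return data frame with `base` and `offset` columns.
#' @export
parse_cds_position <- function(x) {
  tok <- gsub("[[:space:]]", "", as.character(x))
  m <- regmatches(tok, regexec(sprintf("^%s$", .coord_re), tok))
  bad <- vapply(m, length, 1L) == 0L | vapply(m, function(p) length(p) && p[1] == "", TRUE)
  if (any(bad)) {
    stop_rorscan(
      sprintf("cannot parse CDS position: %s", paste(unique(x[bad]), collapse = ", ")),
      "parse_error"
    )
  }
  base <- as.integer(vapply(m, `[`, "", 2))
  off <- vapply(m, `[`, "", 3)
  data.frame(
    base = base,
    offset = ifelse(off == "", 0L, suppressWarnings(as.integer(off))),
    stringsAsFactors = FALSE
  )
}

#' Format a CDS coordinate back to its position token
#'
#' Inverse of [parse_cds_position()]: `format_cds_position(5468, -1)` is
#' `"5468-1"`.
#'
#' @param base integer CDS base.
#' @param offset signed intronic offset (0 for exonic).
#' @return character vector of tokens.
#' @export
format_cds_position <- function(base, offset = 0L) {
  paste0(base, ifelse(offset == 0L, "", sprintf("%+d", offset)))
}

#' Compare two CDS coordinates
#'
#' Total order consistent with transcript direction: lexicographic in
#' (base, offset), so `5468-1 < 5468 < 5468+1`.
#'
#' @param a,b lists or one-row data frames with `base` and `offset`.
#' @return -1, 0 or 1.
#' @export
compare_cds <- function(a, b) {
  ab <- a$base[1]
  bb <- b$base[1]
  ao <- (a$offset %||% 0L)[1]
  bo <- (b$offset %||% 0L)[1]
  if (ab != bb) {
    return(sign(ab - bb))
  }
  sign(ao - bo)
}

#' Sort a table of CDS coordinates
#'
#' @param coords data frame with `base` and (optionally) `offset` columns.
#' @return the same data frame, sorted by (base, offset).
#' @export
sort_cds <- function(coords) {
  off <- coords$offset %||% rep(0L, nrow(coords))
  coords[order(coords$base, off), , drop = FALSE]
}

# numeric sort key; intronic offsets in this package's scope are < 1e6 so the
# lexicographic (base, offset) order is preserved
cds_numkey <- function(base, offset = 0L) base + offset * 1e-6
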