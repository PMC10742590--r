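IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Load a cis-element dictionary
#'
#' The dictionary is a TSV of named promoter elements (name, IUPAC pattern,
#' category), the user-editable stand-in for a cis-element database query.
#' Categories follow the plant-promoter convention: `light`, `hormone`,
#' `stress`, `other`.
#'
#' @param path Path to a TSV with columns `name`, `pattern`, `category`.
#' @return A validated tibble.
#' @export
load_element_dictionary <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("name", "pattern", "category") %in% names(d))) {
    stop("load_element_dictionary(): need columns name, pattern, category")
  }
  dup <- unique(d$name[duplicated(d$name)])
  if (length(dup) > 0) {
    stop("load_element_dictionary(): duplicate element name(s): ",
         paste(dup, collapse = ", "))
  }
  if (any(!nzchar(d$pattern))) {
    stop("load_element_dictionary(): empty pattern for ",
         paste(d$name[!nzchar(d$pattern)], collapse = ", "))
  }
  d$pattern <- toupper(d$pattern)
  bad <- vapply(strsplit(d$pattern, "", fixed = TRUE),
                function(ch) any(!ch %in% IUPAC_CODES), logical(1))
  if (any(bad)) {
    stop("load_element_dictionary(): invalid IUPAC code in entry ",
         paste(d$name[bad], collapse = ", "))
  }
  if (!all(d$category %in% c("light", "hormone", "stress", "other"))) {
    stop("load_element_dictionary(): category must be one of ",
         "light/hormone/stress/other")
  }
  tibble::as_tibble(d[c("name", "pattern", "category")])
}

#' The packaged plant cis-element dictionary
#'
#' A curated transcription of commonly used PlantCARE element consensi for
#' the light-, hormone- and stress-responsive elements analysed in plant
#' UGT promoter surveys. Editable: copy the file, modify, and pass your own
#' path to [load_element_dictionary()].
#'
#' @return The dictionary tibble.
#' @export
plantcare_dictionary <- function() {
  load_element_dictionary(
    system.file("extdata", "cis_elements.tsv", package = "ugtfam")
  )
}

#' Scan promoter sequences for dictionary elements
#'
#' Reports every (by default overlapping) occurrence of each element on both
#' strands; IUPAC codes in patterns match their base sets (via
#' [Biostrings::matchPattern()] with `fixed = "subject"`). `start` is the
#' 1-based promoter coordinate of the leftmost matched base regardless of
#' strand. Hits are ordered by position, then strand (+ before -), then
#' element name.
#'
#' @param promoters Tibble with columns `gene_id` and `promoter` (e.g. from
#'   [extract_upstream()]), or a named character vector.
#' @param dictionary Dictionary tibble from [load_element_dictionary()].
#' @param overlapping Keep overlapping matches (default TRUE); otherwise a
#'   greedy left-to-right non-overlapping subset is kept per element and
#'   strand.
#' @return A tibble with `gene_id`, `element`, `category`, `start`,
#'   `strand`, `match`.
#' @export
scan_promoters <- function(promoters, dictionary, overlapping = TRUE) {
  if (is.character(promoters)) {
    promoters <- tibble::tibble(gene_id = names(promoters),
                                promoter = unname(promoters))
  }
  names(promoters)[names(promoters) == "seq"] <- "promoter"
  one <- function(id, seq) {
    if (!nzchar(seq)) return(NULL)
    subj <- Biostrings::DNAString(seq)
    purrr::pmap_dfr(dictionary, function(name, pattern, category) {
      hits <- list()
      plus <- Biostrings::matchPattern(pattern, subj, fixed = "subject")
      if (length(plus) > 0) {
        hits$p <- tibble::tibble(start = BiocGenerics::start(plus),
                                 strand = "+")
      }
      rc <- revcomp(pattern)
      minus <- Biostrings::matchPattern(rc, subj, fixed = "subject")
      if (length(minus) > 0) {
        hits$m <- tibble::tibble(start = BiocGenerics::start(minus),
                                 strand = "-")
      }
      h <- dplyr::bind_rows(hits)
      if (nrow(h) == 0) return(NULL)
      if (!overlapping) {
        w <- nchar(pattern)
        h <- h %>%
          dplyr::group_by(.data$strand) %>%
          dplyr::arrange(.data$start, .by_group = TRUE) %>%
          dplyr::filter({
            keep <- logical(dplyr::n()); last_end <- -1
            for (i in seq_along(keep)) {
              if (.data$start[i] > last_end) {
                keep[i] <- TRUE; last_end <- .data$start[i] + w - 1
              }
            }
            keep
          }) %>%
          dplyr::ungroup()
      }
      h %>% dplyr::mutate(
        gene_id = id, element = name, category = category,
        match = substring(seq, .data$start, .data$start + nchar(pattern) - 1)
      )
    })
  }
  out <- purrr::map2_dfr(promoters$gene_id, promoters$promoter, one)
  if (nrow(out) == 0) {
    return(tibble::tibble(gene_id = character(0), element = character(0),
                          category = character(0), start = integer(0),
                          strand = character(0), match = character(0)))
  }
  out %>%
    dplyr::select("gene_id", "element", "category", "start", "strand",
                  "match") %>%
    dplyr::arrange(.data$gene_id, .data$start, .data$strand, .data$element)
}

default_category_bins <- function() {
  list(
    light = list(breaks = c(-Inf, 0, 5, 6, 10, Inf),
                 labels = c("0", "1-5", "6", "7-10", ">10")),
    hormone = list(breaks = c(-Inf, 0, 5, 7, Inf),
                   labels = c("0", "1-5", "6-7", ">7")),
    stress = list(breaks = c(-Inf, 0, 4, Inf),
                  labels = c("0", "1-4", ">4"))
  )
}

#' Per-gene cis-element counts by category, with binned summaries
#'
#' Counts hits per gene and category (zero-filled over `gene_ids`), and bins
#' the three main categories with configurable edges. The default bins echo
#' the count brackets conventionally reported for plant promoter surveys
#' (light: 0, 1-5, 6, 7-10, >10; hormone: 0, 1-5, 6-7, >7; stress: 0, 1-4,
#' >4).
#'
#' @param hits Tibble from [scan_promoters()].
#' @param gene_ids Character vector of all genes scanned (so genes with zero
#'   hits are reported).
#' @param bins Named list of `list(breaks =, labels =)` per category;
#'   default [default_category_bins()].
#' @return A list of class `promoter_counts`: `counts` (wide per-gene tibble)
#'   and `bins` (tibble of category, bin, n_genes).
#' @export
categorize_counts <- function(hits, gene_ids, bins = default_category_bins()) {
  cats <- c("light", "hormone", "stress", "other")
  counts <- hits %>%
    dplyr::count(.data$gene_id, .data$category) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0) %>%
    dplyr::right_join(tibble::tibble(gene_id = gene_ids), by = "gene_id")
  for (cat in cats) {
    if (!cat %in% names(counts)) counts[[cat]] <- 0L
    counts[[cat]][is.na(counts[[cat]])] <- 0L
  }
  counts <- counts %>%
    dplyr::select("gene_id", dplyr::all_of(cats)) %>%
    dplyr::arrange(.data$gene_id)
  binned <- purrr::imap_dfr(bins, function(spec, cat) {
    b <- cut(counts[[cat]], breaks = spec$breaks, labels = spec$labels)
    tibble::as_tibble(table(bin = b), n = "n_genes") %>%
      dplyr::mutate(category = cat, .before = 1)
  })
  structure(list(counts = counts, bins = binned), class = "promoter_counts")
}

#' @export
print.promoter_counts <- function(x, ...) {
  cat("Promoter cis-element counts for", nrow(x$counts), "gene(s)\n")
  print(x$bins, n = Inf)
  invisible(x)
}
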