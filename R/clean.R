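#' Filter occurrence records to complete species names
#'
#' Keeps records whose name looks like a full Latinized binomial (or
#' trinomial); rejects entries that are not complete species names:
#' single words (bare genus or place names), qualifiers such as `sp.` /
#' `spp.`, single-letter epithets ("Calanus a"), `cf.`/`aff.` qualified
#' identifications, and names containing digits.
#'
#' @param records data.frame with at least a `species` column.
#' @param name_col Name of the column holding the taxon name.
#' @return A list with `kept` (the surviving rows), `rejected` (the
#'   dropped rows plus a `reason` column), and `report` (a named count of
#'   rejections per reason).
#' @examples
#' r <- data.frame(species = c("Calanus finmarchicus", "Calanus sp.",
#'                             "Calanus a", "Diatoms"))
#' clean_names(r)$report
#' @export
clean_names <- function(records, name_col = "species") {
  if (!name_col %in% names(records))
    stop("records lack a `", name_col, "` column", call. = FALSE)
  nm <- trimws(as.character(records[[name_col]]))
  if (anyNA(nm) || any(!nzchar(nm)))
    stop("every record needs a nonempty name", call. = FALSE)

  tokens <- strsplit(nm, "[[:space:]]+")
  ntok <- lengths(tokens)
  second <- vapply(tokens, function(t) if (length(t) >= 2) t[[2]] else "", "")

  reason <- rep(NA_character_, length(nm))
  reason[grepl("[0-9]", nm)] <- "contains_digits"
  is_qual <- grepl("^spp?\\.?$", second, ignore.case = TRUE) |
    grepl("[[:space:]]spp?\\.$", nm, ignore.case = TRUE)
  reason[is.na(reason) & is_qual] <- "sp_qualifier"
  reason[is.na(reason) &
           grepl("^(cf|aff)\\.?$", second, ignore.case = TRUE)] <- "cf_aff_qualifier"
  reason[is.na(reason) & ntok >= 2 & nchar(second) == 1] <- "single_letter_epithet"
  reason[is.na(reason) & ntok < 2] <- "single_word"

  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  report <- if (any(!keep)) table(reason[!keep]) else table(character())
  list(kept = records[keep, , drop = FALSE],
       rejected = rejected,
       report = as.list(report))
}

#' Read occurrence records from delimited text
#'
#' @param path File path; the delimiter is sniffed from the header line
#'   (tab if present, else comma).
#' @param columns Named character vector mapping internal fields
#'   (`species`, `lat`, `lon`, and optionally `genus`, `phylum`,
#'   `pelagic`) to the file's column names.
#' @return data.frame with standardized column names `species`, `lat`,
#'   `lon` plus any of the optional fields found.
#' @export
read_occurrences <- function(path,
                             columns = c(species = "species",
                                         lat = "decimalLatitude",
                                         lon = "decimalLongitude",
                                         genus = "genus",
                                         phylum = "phylum",
                                         pelagic = "pelagic")) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species", "lat", "lon")
  miss <- setdiff(columns[need], names(df))
  if (length(miss))
    stop("input lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(species = as.character(df[[columns[["species"]]]]),
                    lat = as.numeric(df[[columns[["lat"]]]]),
                    lon = as.numeric(df[[columns[["lon"]]]]),
                    stringsAsFactors = FALSE)
  for (f in c("genus", "phylum", "pelagic"))
    if (f %in% names(columns) && columns[[f]] %in% names(df))
      out[[f]] <- df[[columns[[f]]]]
  out
}

#' Write occurrence records as delimited text
#'
#' Emits the standard header `species, genus, phylum, pelagic,
#' decimalLatitude, decimalLongitude` (optional columns filled with
#' blanks/zero if absent).
#'
#' @param records data.frame with `species`, `lat`, `lon` and optionally
#'   `genus`, `phylum`, `pelagic`.
#' @param path Output file path.
#' @param sep Field delimiter.
#' @export
write_occurrences <- function(records, path, sep = ",") {
  out <- data.frame(
    species = records$species,
    genus = if (!is.null(records$genus)) records$genus
            else vapply(strsplit(records$species, "[[:space:]]+"), `[`, "", 1L),
    phylum = if (!is.null(records$phylum)) records$phylum else "",
    pelagic = if (!is.null(records$pelagic)) as.integer(records$pelagic) else 0L,
    decimalLatitude = records$lat,
    decimalLongitude = records$lon,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
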