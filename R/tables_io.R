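# ---- column aliasing -------------------------------------------------------

# canonical name -> accepted aliases (matched case-insensitively after
# stripping units in parentheses, whitespace, '-', '_' and '.')
.soil_aliases <- list(
  sample_id = c("sampleid", "sample", "samples", "site", "id"),
  som = c("som", "somgkg", "organicmatter"),
  ph  = c("ph"),
  cec = c("cec", "ceccmolkg"),
  ec  = c("ec", "ecmsm"),
  clay = c("clay", "claypct"),
  silt = c("silt", "siltpct"),
  sand = c("sand", "sandpct"),
  tn = c("tn", "tngkg", "totalnitrogen"),
  an = c("an", "anmgkg"),
  ap = c("ap", "apmgkg"),
  ak = c("ak", "akmgkg")
)

.norm_header <- function(x) {
  x <- gsub("\\(.*?\\)", "", x)
  tolower(gsub("[^A-Za-z0-9]", "", x))
}

.match_columns <- function(header, aliases, required = TRUE, context = "table") {
  norm <- .norm_header(header)
  out <- integer(0)
  for (canon in names(aliases)) {
    hit <- which(norm %in% c(canon, .norm_header(aliases[[canon]])))
    if (length(hit) == 0) {
      if (required)
        stop(sprintf("%s: required column '%s' not found (header: %s)",
                     context, canon, paste(header, collapse = ", ")),
             call. = FALSE)
      next
    }
    out[canon] <- hit[1]
  }
  out
}

# all columns are read as character so a blank cell (parse error) can be
# told apart from an explicit "NA" token (allowed where stated)
.read_delim_table <- function(path, delim = c("tab", "comma")) {
  delim <- match.arg(delim)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = if (delim == "tab") "\t" else ",",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", na.strings = character(0),
                    comment.char = "", quote = "\"")
}

.numeric_column <- function(raw, col_name, context, allow_na = FALSE) {
  raw <- as.character(raw)
  tw <- trimws(raw)
  blank <- which(is.na(raw) | !nzchar(tw))
  if (length(blank))
    stop(sprintf("%s: blank value in column '%s', row %d",
                 context, col_name, blank[1]), call. = FALSE)
  na_tok <- toupper(tw) == "NA"
  v <- suppressWarnings(as.numeric(tw))
  bad <- which(!na_tok & is.na(v))
  if (length(bad))
    stop(sprintf("%s: non-numeric value '%s' in column '%s', row %d",
                 context, raw[bad[1]], col_name, bad[1]), call. = FALSE)
  if (any(na_tok)) {
    if (!allow_na)
      stop(sprintf("%s: missing value in column '%s', row %d",
                   context, col_name, which(na_tok)[1]), call. = FALSE)
    message(sprintf("%s: %d NA value(s) in column '%s'",
                    context, sum(na_tok), col_name))
  }
  v
}

# ---- soil profile table ----------------------------------------------------

#' Read a soil physicochemical property table
#'
#' Reads a per-sample table of soil properties: soil organic matter (SOM,
#' g/kg), pH, cation exchange capacity (CEC, cmol/kg), electrical
#' conductivity (EC, ms/m), texture fractions (clay/silt/sand, percent),
#' total nitrogen (TN, g/kg) and available N/P/K (mg/kg). Header names are
#' matched case-insensitively against an alias map (e.g. `"SOM(g/kg)"`,
#' `"som"`); explicit `NA` tokens are allowed and counted, blank cells are a
#' parse error.
#'
#' @param path path to a delimited text file with a header row.
#' @param delim `"tab"` (default) or `"comma"`.
#' @return a `soil_profile_table`: a data frame with columns `sample_id`,
#'   `som`, `ph`, `cec`, `ec`, `clay`, `silt`, `sand`, `tn`, `an`, `ap`,
#'   `ak`, row order preserved.
#' @examples
#' tab1 <- read_soil_table(system.file("extdata", "table1.tsv",
#'                                     package = "paddynet"))
#' mean(tab1$ph)
#' @export
read_soil_table <- function(path, delim = c("tab", "comma")) {
  df <- .read_delim_table(path, delim)
  idx <- .match_columns(names(df), .soil_aliases, context = "soil table")
  out <- data.frame(sample_id = as.character(df[[idx["sample_id"]]]),
                    stringsAsFactors = FALSE)
  for (canon in setdiff(names(.soil_aliases), "sample_id"))
    out[[canon]] <- .numeric_column(df[[idx[canon]]], canon, "soil table",
                                    allow_na = TRUE)
  validate_soil_table(out)
}

#' Validate a soil profile table
#'
#' Checks sample-id uniqueness, value ranges (pH in (0,14), non-negative
#' concentrations) and that clay + silt + sand sums to 100 within +/- 0.5
#' per sample (printed textures are rounded to 2 decimals).
#'
#' @param x a data frame with the `soil_profile_table` columns.
#' @return `x` with class `soil_profile_table` prepended.
#' @export
validate_soil_table <- function(x) {
  if (anyDuplicated(x$sample_id))
    stop("soil table: duplicated sample_id", call. = FALSE)
  ok_ph <- is.na(x$ph) | (x$ph > 0 & x$ph < 14)
  if (!all(ok_ph)) stop("soil table: pH outside (0, 14)", call. = FALSE)
  conc <- c("som", "cec", "ec", "clay", "silt", "sand", "tn", "an", "ap", "ak")
  for (cn in conc)
    if (any(x[[cn]] < 0, na.rm = TRUE))
      stop("soil table: negative value in column '", cn, "'", call. = FALSE)
  tex <- x$clay + x$silt + x$sand
  bad <- which(!is.na(tex) & abs(tex - 100) > 0.5)
  if (length(bad))
    stop("soil table: clay+silt+sand outside 100 +/- 0.5 for sample(s): ",
         paste(x$sample_id[bad], collapse = ", "), call. = FALSE)
  class(x) <- c("soil_profile_table", "data.frame")
  x
}

#' Write a soil profile table
#' @param x a `soil_profile_table`.
#' @param path output path.
#' @param delim `"tab"` or `"comma"`.
#' @return `path`, invisibly.
#' @export
write_soil_table <- function(x, path, delim = c("tab", "comma")) {
  .write_table(x, path, delim)
}

.write_table <- function(x, path, delim = c("tab", "comma")) {
  delim <- match.arg(delim)
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = if (delim == "tab") "\t" else ",",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- metal table -----------------------------------------------------------

#' Read a heavy-metal concentration table
#'
#' Reads per-sample total and DTPA-extractable metal concentrations (mg/kg).
#' Column headers of the form `T-Cd`/`A-Cd` (or `total_cd`/`dtpa_cd`) are
#' recognised for any metal; Cd, Cu, Pb and Zn are required, extra metals
#' are carried through. A `PLI` column, if present, is kept as
#' `pli_reported` for reference. Rows where a DTPA fraction exceeds the
#' total trigger a warning (not an error).
#'
#' @inheritParams read_soil_table
#' @return a `metal_table`: a data frame with `sample_id`, `total_<Metal>`
#'   and `dtpa_<Metal>` columns, attribute `metals` listing metal names.
#' @examples
#' tab2 <- read_metal_table(system.file("extdata", "table2.tsv",
#'                                      package = "paddynet"))
#' attr(tab2, "metals")
#' @export
read_metal_table <- function(path, delim = c("tab", "comma")) {
  df <- .read_delim_table(path, delim)
  header <- names(df)
  norm <- .norm_header(header)
  id_idx <- which(norm %in% c("sampleid", "sample", "samples", "site", "id"))
  if (!length(id_idx)) stop("metal table: no sample id column", call. = FALSE)
  out <- data.frame(sample_id = as.character(df[[id_idx[1]]]),
                    stringsAsFactors = FALSE)
  metals <- character(0)
  for (j in seq_along(header)) {
    h <- norm[j]
    m <- regmatches(h, regexec("^(t|total)([a-z]+)$", h))[[1]]
    a <- regmatches(h, regexec("^(a|dtpa|avail|available)([a-z]+)$", h))[[1]]
    metal <- NULL; kind <- NULL
    if (length(m)) { metal <- m[3]; kind <- "total" }
    else if (length(a)) { metal <- a[3]; kind <- "dtpa" }
    if (is.null(metal)) next
    metal <- paste0(toupper(substr(metal, 1, 1)), substr(metal, 2, nchar(metal)))
    v <- .numeric_column(df[[j]], header[j], "metal table", allow_na = TRUE)
    if (any(v < 0, na.rm = TRUE))
      stop("metal table: negative concentration in column '", header[j], "'",
           call. = FALSE)
    out[[paste0(kind, "_", metal)]] <- v
    metals <- union(metals, metal)
  }
  need <- c("Cd", "Cu", "Pb", "Zn")
  if (!all(need %in% metals))
    stop("metal table: missing required metal column(s): ",
         paste(setdiff(need, metals), collapse = ", "), call. = FALSE)
  if ("pli" %in% norm) out$pli_reported <- .numeric_column(
    df[[which(norm == "pli")[1]]], "PLI", "metal table")
  if (anyDuplicated(out$sample_id))
    stop("metal table: duplicated sample_id", call. = FALSE)
  for (me in metals) {
    tot <- out[[paste0("total_", me)]]; dt <- out[[paste0("dtpa_", me)]]
    if (!is.null(tot) && !is.null(dt) && any(dt > tot, na.rm = TRUE))
      warning(sprintf("metal table: DTPA-extractable %s exceeds total for %d sample(s)",
                      me, sum(dt > tot, na.rm = TRUE)), call. = FALSE)
  }
  attr(out, "metals") <- metals
  class(out) <- c("metal_table", "data.frame")
  out
}

#' Write a metal table
#' @inheritParams write_soil_table
#' @export
write_metal_table <- function(x, path, delim = c("tab", "comma")) {
  .write_table(x, path, delim)
}

#' Read a background concentration table
#'
#' Two columns: `metal` and `background` (mg/kg); extra columns ignored.
#'
#' @inheritParams read_soil_table
#' @return named numeric vector of strictly positive backgrounds.
#' @export
read_background_table <- function(path, delim = c("tab", "comma")) {
  df <- .read_delim_table(path, delim)
  norm <- .norm_header(names(df))
  mi <- which(norm == "metal"); bi <- which(norm %in% c("background", "value"))
  if (!length(mi) || !length(bi))
    stop("background table: need 'metal' and 'background' columns", call. = FALSE)
  bg <- .numeric_column(df[[bi[1]]], "background", "background table")
  if (any(bg <= 0)) stop("background table: backgrounds must be > 0", call. = FALSE)
  stats::setNames(bg, as.character(df[[mi[1]]]))
}

# ---- OTU table -------------------------------------------------------------

#' Construct an OTU count table
#'
#' @param counts non-negative integer matrix, samples in rows, taxa in
#'   columns; dimnames give sample and OTU ids.
#' @param taxonomy optional named character vector of semicolon-separated
#'   lineage strings (domain...genus, `"Unclassified"` allowed), one per OTU.
#' @return an `otu_table`: a list with elements `counts` and `taxonomy`.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("OTU_", seq_len(ncol(counts)))
  if (anyDuplicated(colnames(counts)))
    stop("otu table: duplicated otu_id", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("otu table: duplicated sample_id", call. = FALSE)
  if (any(counts < 0)) stop("otu table: negative count", call. = FALSE)
  frac <- abs(counts - round(counts))
  if (any(frac > 1e-6))
    stop("otu table: non-integer count beyond tolerance 1e-6", call. = FALSE)
  storage.mode(counts) <- "integer"
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop("otu table: all-zero sample(s): ",
         paste(rownames(counts)[zero], collapse = ", "), call. = FALSE)
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) names(taxonomy) <- colnames(counts)
    taxonomy <- taxonomy[colnames(counts)]
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d taxa, total reads %.0f\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Read an OTU count table from delimited text
#'
#' The body must be numeric; counts are coerced to integers (fractional
#' values beyond 1e-6 are an error). A trailing `taxonomy` column (when taxa
#' are rows) is split off into the lineage map. Orientation is normalised to
#' samples x taxa.
#'
#' @param path path to a delimited file; first column holds row ids.
#' @param orientation `"taxa_rows"` (default; OTUs in rows, samples in
#'   columns, the common QIIME layout) or `"samples_rows"`.
#' @param delim `"tab"` or `"comma"`.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, orientation = c("taxa_rows", "samples_rows"),
                           delim = c("tab", "comma")) {
  orientation <- match.arg(orientation)
  df <- .read_delim_table(path, delim)
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  taxonomy <- NULL
  tax_col <- which(.norm_header(names(df)) %in% c("taxonomy", "lineage"))
  if (length(tax_col)) {
    if (orientation == "taxa_rows")
      taxonomy <- stats::setNames(as.character(df[[tax_col[1]]]), ids)
    df <- df[, -tax_col, drop = FALSE]
  }
  raw <- as.matrix(df)
  mat <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw),
                                 dimnames = dimnames(raw)))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    stop("otu table: non-numeric cell at row ", ids[bad[1, 1]], ", column ",
         colnames(mat)[bad[1, 2]], call. = FALSE)
  }
  rownames(mat) <- ids
  if (orientation == "taxa_rows") mat <- t(mat)
  otu_table(mat, taxonomy)
}

#' Write an OTU table (samples x taxa, optional taxonomy column)
#' @param x an [otu_table].
#' @param path output path.
#' @param orientation layout to write, see [read_otu_table].
#' @param delim `"tab"` or `"comma"`.
#' @export
write_otu_table <- function(x, path, orientation = c("taxa_rows", "samples_rows"),
                            delim = c("tab", "comma")) {
  orientation <- match.arg(orientation)
  delim <- match.arg(delim)
  sep <- if (delim == "tab") "\t" else ","
  if (orientation == "taxa_rows") {
    df <- as.data.frame(t(x$counts))
    df <- cbind(otu_id = rownames(df), df)
    if (!is.null(x$taxonomy)) df$taxonomy <- x$taxonomy[df$otu_id]
  } else {
    df <- as.data.frame(x$counts)
    df <- cbind(sample_id = rownames(df), df)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an OTU table from a BIOM (2.1 or 1.0) file
#'
#' Thin wrapper over the `biomformat` package; returns the same container
#' as [read_otu_table].
#'
#' @param path path to a BIOM file.
#' @return an [otu_table].
#' @export
read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("read_otu_biom() requires the 'biomformat' package", call. = FALSE)
  b <- biomformat::read_biom(path)
  mat <- as.matrix(biomformat::biom_data(b))  # taxa x samples
  otu_table(t(mat))
}

#' Packaged fixture tables from the field survey
#'
#' Returns the 15 printed site rows of the soil-property and metal tables
#' together with the regional background concentrations used for
#' contamination factors (Cd 0.11 and Pb 20.78 mg/kg are regional
#' background values; Cu 22.3 and Zn 62.6 mg/kg are back-solved from the
#' printed pollution load indices and marked as such in the fixture file).
#'
#' @return list with elements `soil` ([read_soil_table] result), `metals`
#'   ([read_metal_table] result) and `backgrounds` (named numeric).
#' @examples
#' fx <- paper_fixture()
#' round(mean(fx$soil$ph), 2)
#' @export
paper_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "paddynet")
  list(soil = read_soil_table(ext("table1.tsv")),
       metals = suppressWarnings(read_metal_table(ext("table2.tsv"))),
       backgrounds = read_background_table(ext("backgrounds.tsv")))
}
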