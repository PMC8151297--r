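#' @useDynLib capspop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbeta runif rnorm sd var setNames
#' @importFrom utils combn read.delim write.table
"_PACKAGE"

NUCLEOTIDES <- c("A", "C", "G", "T")
MISSING_CALL <- "-/-"

#' Construct a codominant genotype matrix
#'
#' A `genotype_matrix` holds diploid, codominant calls for a panel of
#' accessions typed at a set of biallelic (or, in principle, multiallelic)
#' nucleotide markers. Each cell is an unordered allele pair such as
#' `"A/G"`; missing data are `NA` internally and `"-/-"` on disk.
#'
#' @param calls character matrix (accessions x markers) of `"X/Y"` calls;
#'   `NA` or `"-/-"` for missing. Calls are normalized: trimmed, upper-cased,
#'   allele pairs sorted so `"G/A"` and `"A/G"` are identical.
#' @param accession_ids unique accession labels; defaults to rownames.
#' @param marker_ids unique marker labels; defaults to colnames.
#' @param populations optional per-accession population labels (required by
#'   [amova_codominant()], ignored by diversity statistics).
#' @return object of class `genotype_matrix` with elements `accession_ids`,
#'   `marker_ids`, `calls`, `populations`.
#' @examples
#' gm <- genotype_matrix(matrix(c("A/A", "G/A", "G/G", "-/-"), 2, 2,
#'   dimnames = list(c("x", "y"), c("m1", "m2"))))
#' gm$calls  # "G/A" has been normalized to "A/G"
#' @export
genotype_matrix <- function(calls, accession_ids = rownames(calls),
                            marker_ids = colnames(calls),
                            populations = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  force(accession_ids)
  force(marker_ids)
  calls <- matrix(as.character(calls), nrow(calls), ncol(calls))
  if (is.null(accession_ids) || is.null(marker_ids)) {
    stop("accession and marker ids are required (names or arguments)")
  }
  accession_ids <- as.character(accession_ids)
  marker_ids <- as.character(marker_ids)
  if (length(accession_ids) != nrow(calls)) {
    stop("length(accession_ids) != nrow(calls)")
  }
  if (length(marker_ids) != ncol(calls)) {
    stop("length(marker_ids) != ncol(calls)")
  }
  if (anyDuplicated(accession_ids)) {
    stop("duplicate accession ids: ",
         paste(unique(accession_ids[duplicated(accession_ids)]), collapse = ", "))
  }
  if (anyDuplicated(marker_ids)) {
    stop("duplicate marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  }
  norm <- vapply(seq_along(calls), function(i) {
    normalize_call(calls[[i]], context = cell_name(i, accession_ids, marker_ids))
  }, character(1))
  calls <- matrix(norm, nrow(calls), ncol(calls),
                  dimnames = list(accession_ids, marker_ids))
  if (!is.null(populations)) {
    populations <- as.character(populations)
    if (length(populations) != length(accession_ids)) {
      stop("length(populations) != number of accessions")
    }
    names(populations) <- accession_ids
  }
  structure(list(accession_ids = accession_ids, marker_ids = marker_ids,
                 calls = calls, populations = populations),
            class = "genotype_matrix")
}

# Internal fast path: calls already normalized by construction.
new_genotype_matrix <- function(calls, populations = NULL) {
  acc <- rownames(calls)
  mk <- colnames(calls)
  if (!is.null(populations)) names(populations) <- acc
  structure(list(accession_ids = acc, marker_ids = mk, calls = calls,
                 populations = populations),
            class = "genotype_matrix")
}

cell_name <- function(i, acc, mk) {
  n <- length(acc)
  paste0(acc[(i - 1L) %% n + 1L], " @ ", mk[(i - 1L) %/% n + 1L])
}

#' Normalize a single diploid call
#'
#' Trims whitespace, upper-cases, sorts the two alleles, and maps the missing
#' sentinel `"-/-"` to `NA`. Half-missing calls (one allele missing) and
#' non-nucleotide symbols are rejected. Idempotent.
#'
#' @param x a call string such as `"g/a"`, `"A/G"`, `"-/-"`, or `NA`.
#' @param context label used in error messages (e.g. the offending cell).
#' @return normalized call string or `NA_character_`.
#' @export
normalize_call <- function(x, context = NULL) {
  where <- if (is.null(context)) "" else paste0(" at ", context)
  if (is.na(x)) return(NA_character_)
  x <- toupper(gsub("[[:space:]]", "", x))
  parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L || any(!nzchar(parts))) {
    stop("malformed call '", x, "'", where, " (expected 'X/Y')")
  }
  miss <- parts == "-"
  if (all(miss)) return(NA_character_)
  if (any(miss)) {
    stop("half-missing call '", x, "'", where,
         " (both alleles must be present or both missing)")
  }
  bad <- setdiff(parts, NUCLEOTIDES)
  if (length(bad)) {
    stop("non-nucleotide symbol '", bad[1], "' in call '", x, "'", where)
  }
  paste(sort(parts), collapse = "/")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d markers\n",
              length(x$accession_ids), length(x$marker_ids)))
  nm <- sum(is.na(x$calls))
  cat(sprintf("  missing calls: %d (%.1f%%)\n", nm,
              100 * nm / length(x$calls)))
  if (!is.null(x$populations)) {
    tb <- table(x$populations)
    cat("  populations:", paste(sprintf("%s=%d", names(tb), tb),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Read a genotype table from TSV/CSV
#'
#' First column holds accession ids, the header row marker ids, and every
#' remaining cell a call such as `"A/G"` or `"-/-"`. Calls are normalized on
#' read (see [normalize_call()]).
#'
#' @param path file path.
#' @param sep field separator; default tab.
#' @param populations optional per-accession population labels, or the path
#'   of a two-column (accession, population) TSV.
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path, sep = "\t", populations = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2L) stop("genotype table needs >=1 marker column")
  acc <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- acc
  if (is.character(populations) && length(populations) == 1L &&
      file.exists(populations)) {
    pf <- read.delim(populations, sep = sep, header = TRUE,
                     colClasses = "character")
    populations <- setNames(pf[[2]], pf[[1]])[acc]
  }
  gm <- genotype_matrix(m, populations = populations)
  message(sprintf("read %d accessions x %d markers from %s",
                  nrow(m), ncol(m), path))
  gm
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]; missing calls are written as `"-/-"`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param sep field separator.
#' @export
write_genotype_table <- function(gm, path, sep = "\t") {
  m <- gm$calls
  m[is.na(m)] <- MISSING_CALL
  df <- data.frame(accession = gm$accession_ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CAPS marker definition table
#'
#' Expects tab/comma-separated columns `marker_id`, `locus_desc`,
#' `chromosome`, `substitution`, `ref`, `alt`, `enzyme`, `temp_c`,
#' `primer_left`, `primer_right`. The transition/transversion class is
#' recomputed from the ref/alt alleles and must agree with the stated label.
#'
#' @param path file path; defaults to the packaged 70-marker CAPS panel for
#'   *Agaricus bisporus* (button mushroom).
#' @param sep field separator.
#' @return data.frame of marker definitions with a recomputed
#'   `substitution_class` column.
#' @export
read_marker_table <- function(path = system.file("extdata",
                                                 "table2_markers.tsv",
                                                 package = "capspop"),
                              sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = sep, header = TRUE, colClasses = "character")
  need <- c("marker_id", "ref", "alt", "enzyme")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("marker table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$marker_id)) stop("duplicate marker ids in ", path)
  df$ref <- toupper(df$ref)
  df$alt <- toupper(df$alt)
  df$substitution_class <- mapply(classify_substitution, df$ref, df$alt,
                                  USE.NAMES = FALSE)
  if ("substitution" %in% names(df)) {
    stated <- tolower(df$substitution)
    bad <- which(stated != df$substitution_class)
    if (length(bad)) {
      stop("stated substitution class conflicts with ref/alt for marker(s): ",
           paste(df$marker_id[bad], collapse = ", "))
    }
  }
  if ("temp_c" %in% names(df)) df$temp_c <- as.numeric(df$temp_c)
  pr <- c("primer_left", "primer_right")
  for (p in intersect(pr, names(df))) {
    seqs <- toupper(df[[p]])
    ok <- nzchar(seqs) & !grepl("[^ACGTRYSWKMBDHVN]", seqs)
    if (!all(ok)) stop("non-IUPAC primer for marker(s): ",
                       paste(df$marker_id[!ok], collapse = ", "))
    df[[p]] <- seqs
  }
  df
}

#' Validate a genotype matrix against marker definitions
#'
#' Checks that every observed allele at a marker is one of that marker's
#' ref/alt alleles, and reports per-marker missingness and monomorphism.
#'
#' @param gm a [genotype_matrix()].
#' @param defs marker definitions from [read_marker_table()].
#' @return list with `violations` (data.frame: accession, marker, call),
#'   `per_marker` (data.frame: marker_id, n_missing, missingness,
#'   monomorphic), and `missingness` (overall rate).
#' @export
validate_against_markers <- function(gm, defs) {
  unknown <- setdiff(gm$marker_ids, defs$marker_id)
  if (length(unknown)) {
    stop("marker id(s) absent from definitions: ",
         paste(unknown, collapse = ", "))
  }
  idx <- match(gm$marker_ids, defs$marker_id)
  viol <- list()
  per <- data.frame(marker_id = gm$marker_ids,
                    n_missing = integer(length(gm$marker_ids)),
                    missingness = 0, monomorphic = NA)
  for (j in seq_along(gm$marker_ids)) {
    col <- gm$calls[, j]
    ok_alleles <- c(defs$ref[idx[j]], defs$alt[idx[j]])
    nm <- is.na(col)
    per$n_missing[j] <- sum(nm)
    per$missingness[j] <- mean(nm)
    obs <- unique(unlist(strsplit(col[!nm], "/", fixed = TRUE)))
    per$monomorphic[j] <- length(obs) <= 1L
    off <- vapply(strsplit(col, "/", fixed = TRUE), function(a) {
      !is.null(a) && length(setdiff(a, ok_alleles)) > 0
    }, logical(1))
    off[nm] <- FALSE
    if (any(off)) {
      viol[[length(viol) + 1L]] <- data.frame(
        accession = gm$accession_ids[off], marker = gm$marker_ids[j],
        call = col[off], stringsAsFactors = FALSE)
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(accession = character(), marker = character(),
               call = character(), stringsAsFactors = FALSE)
  list(violations = violations, per_marker = per,
       missingness = mean(is.na(gm$calls)))
}

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param accessions,markers character or integer index vectors (default all).
#' @return a [genotype_matrix()].
#' @export
subset_genotypes <- function(gm, accessions = NULL, markers = NULL) {
  ai <- if (is.null(accessions)) seq_along(gm$accession_ids) else accessions
  mi <- if (is.null(markers)) seq_along(gm$marker_ids) else markers
  calls <- gm$calls[ai, mi, drop = FALSE]
  pops <- if (is.null(gm$populations)) NULL else gm$populations[ai]
  genotype_matrix(calls, populations = pops)
}
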