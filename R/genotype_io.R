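#' Multilocus genotype tables
#'
#' The container for unphased codominant genotypes: individual IDs, locus
#' names, and two allele-label matrices (`a1`, `a2`, individuals x loci)
#' stored in canonical sorted order. Missing genotypes are `NA` in both
#' slots. Populations are carried as a label per individual.
#'
#' @param ids character vector of unique individual IDs.
#' @param loci character vector of locus names.
#' @param a1,a2 character matrices (`length(ids)` x `length(loci)`) of
#'   allele labels; `NA` = missing.
#' @param population optional character vector of population labels per
#'   individual (recycled if length 1).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, loci, a1, a2, population = "pop1") {
  ids <- as.character(ids)
  loci <- as.character(loci)
  if (anyDuplicated(ids)) stop("individual IDs must be unique")
  if (anyDuplicated(loci)) stop("locus names must be unique")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "character"; storage.mode(a2) <- "character"
  if (!all(dim(a1) == c(length(ids), length(loci))) ||
      !all(dim(a2) == c(length(ids), length(loci)))) {
    stop("allele matrices must be length(ids) x length(loci)")
  }
  if (any(is.na(a1) != is.na(a2))) {
    stop("half-missing genotypes are not allowed: both alleles or neither")
  }
  cp <- canon_pair(a1, a2)
  a1 <- cp$a; a2 <- cp$b
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  population <- rep_len(as.character(population), length(ids))
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2,
                 population = population),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat("Genotype table:", length(x$ids), "individuals x", length(x$loci),
      "loci (", length(unique(x$population)), "population(s),",
      sprintf("%.1f%%", 100 * miss), "missing )\n")
  invisible(x)
}

#' Extract one individual's multilocus genotype
#'
#' @param table a [genotype_table()].
#' @param id individual ID.
#' @return A 2 x n_loci character matrix (rows = the two alleles), `NA`
#'   columns for missing loci.
#' @export
genotypes_of <- function(table, id) {
  stopifnot(inherits(table, "genotype_table"))
  i <- match(as.character(id), table$ids)
  if (is.na(i)) stop("unknown individual ID: ", id)
  rbind(a1 = table$a1[i, ], a2 = table$a2[i, ])
}

# ---- GenePop dialect -------------------------------------------------------

#' Read a GenePop file
#'
#' Accepts the common GenePop dialect: a title line, locus names (one per
#' line or comma-separated), `POP` separators, and fixed-width diploid
#' genotype codes. Both 2- and 3-digit allele codes are accepted and
#' auto-detected per file; an all-zero code (`00`/`000` in either allele)
#' marks a missing genotype. Allele labels are preserved as their integer
#' codes (as character, e.g. `"101"`).
#'
#' @param path file path.
#' @return A [genotype_table()]; populations are labelled `pop1`, `pop2`,
#'   ... in file order.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 4L) stop("malformed GenePop file: fewer than 4 lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L) {
    stop("malformed GenePop header: no POP line after locus names (line ",
         first_pop %||% NA, ")")
  }
  loci <- unlist(strsplit(lines[2:(first_pop - 1L)], ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("malformed GenePop header: no locus names")

  ids <- character(); pops <- character()
  rows1 <- list(); rows2 <- list()
  width <- NA_integer_
  pop_i <- 0L
  for (ln in seq(first_pop, length(lines))) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (toupper(trimws(line)) == "POP") { pop_i <- pop_i + 1L; next }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L) {
      stop("line ", ln, ": expected 'id , genotypes'")
    }
    id <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    gts <- gts[nzchar(gts)]
    if (length(gts) != length(loci)) {
      stop("line ", ln, ": ", length(gts), " genotypes for ",
           length(loci), " loci (ragged row)")
    }
    w <- unique(nchar(gts))
    if (length(w) != 1L || !(w %in% c(4L, 6L))) {
      stop("line ", ln, ": allele codes must all be 2- or 3-digit (genotype width 4 or 6)")
    }
    w <- w / 2L
    if (is.na(width)) width <- w
    if (w != width) stop("line ", ln, ": mixed allele-code widths in one file")
    al1 <- substr(gts, 1L, width)
    al2 <- substr(gts, width + 1L, 2L * width)
    if (any(is.na(suppressWarnings(as.integer(c(al1, al2)))))) {
      stop("line ", ln, ": non-numeric allele code")
    }
    miss <- as.integer(al1) == 0L | as.integer(al2) == 0L
    al1[miss] <- NA; al2[miss] <- NA
    # drop leading zeros so that "01" and "001" refer to the same allele
    al1[!miss] <- as.character(as.integer(al1[!miss]))
    al2[!miss] <- as.character(as.integer(al2[!miss]))
    ids <- c(ids, id)
    pops <- c(pops, paste0("pop", max(pop_i, 1L)))
    rows1[[length(rows1) + 1L]] <- al1
    rows2[[length(rows2) + 1L]] <- al2
  }
  if (length(ids) == 0L) stop("GenePop file contains no individuals")
  genotype_table(ids, loci,
                 do.call(rbind, rows1), do.call(rbind, rows2),
                 population = pops)
}

#' @rdname read_genepop
#' @param table a [genotype_table()] with integer-coded allele labels.
#' @param digits allele-code width, 2 or 3.
#' @param title title line to write.
#' @export
write_genepop <- function(table, path, digits = 3L, title = "kindyad export") {
  stopifnot(inherits(table, "genotype_table"), digits %in% c(2L, 3L))
  codes <- suppressWarnings(as.integer(c(table$a1, table$a2)))
  if (any(is.na(codes) & !is.na(c(table$a1, table$a2)))) {
    stop("GenePop export needs integer allele labels")
  }
  fmt <- function(m) {
    v <- suppressWarnings(as.integer(m))
    v[is.na(v)] <- 0L
    matrix(sprintf(paste0("%0", digits, "d"), v), nrow = nrow(m))
  }
  A1 <- fmt(table$a1); A2 <- fmt(table$a2)
  out <- c(title, table$loci)
  for (p in unique(table$population)) {
    out <- c(out, "POP")
    idx <- which(table$population == p)
    out <- c(out, vapply(idx, function(i) {
      paste0(table$ids[i], " , ",
             paste0(A1[i, ], A2[i, ], collapse = " "))
    }, ""))
  }
  writeLines(out, path)
  invisible(path)
}

# ---- CSV dialect -----------------------------------------------------------

#' Read and write genotype tables as CSV
#'
#' Columns: `id`, `population`, then one column per locus holding `"a/b"`
#' allele pairs; an empty cell is a missing genotype.
#'
#' @param path file path.
#' @return `read_genotype_csv()` returns a [genotype_table()].
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!all(c("id", "population") %in% names(df))) {
    stop("genotype CSV needs 'id' and 'population' columns first")
  }
  loci <- setdiff(names(df), c("id", "population"))
  if (length(loci) == 0L) stop("genotype CSV has no locus columns")
  split2 <- function(x) {
    x[!nzchar(trimws(x))] <- NA
    parts <- strsplit(x, "/", fixed = TRUE)
    bad <- !is.na(x) & lengths(parts) != 2L
    if (any(bad)) stop("malformed genotype cell(s): ", paste(x[bad], collapse = ", "))
    list(a = vapply(parts, function(p) if (length(p) == 2L) trimws(p[1]) else NA_character_, ""),
         b = vapply(parts, function(p) if (length(p) == 2L) trimws(p[2]) else NA_character_, ""))
  }
  a1 <- a2 <- matrix(NA_character_, nrow(df), length(loci))
  for (l in seq_along(loci)) {
    sp <- split2(df[[loci[l]]])
    a1[, l] <- sp$a; a2[, l] <- sp$b
  }
  genotype_table(df$id, loci, a1, a2, population = df$population)
}

#' @rdname read_genotype_csv
#' @param table a [genotype_table()].
#' @export
write_genotype_csv <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  cells <- matrix("", length(table$ids), length(table$loci))
  ok <- !is.na(table$a1)
  cells[ok] <- paste0(table$a1[ok], "/", table$a2[ok])
  df <- data.frame(id = table$ids, population = table$population,
                   cells, check.names = FALSE)
  names(df) <- c("id", "population", table$loci)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
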