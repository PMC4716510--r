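#' Allele-frequency sets
#'
#' A `freq_set` holds, per microsatellite locus, the population allele
#' frequencies that enter every likelihood in the package. It is a named
#' list with one element per locus; each element is a named numeric vector
#' (names are allele labels) summing to one, all entries strictly positive.
#'
#' @param x named list of named numeric vectors, one per locus.
#' @return An object of class `freq_set`.
#' @examples
#' fs <- freq_set(list(L1 = c(A = 0.5, B = 0.5)))
#' @export
freq_set <- function(x) {
  if (!is.list(x) || length(x) == 0L || is.null(names(x)) ||
      anyDuplicated(names(x)) || any(!nzchar(names(x)))) {
    stop("'x' must be a non-empty named list with unique locus names")
  }
  out <- lapply(names(x), function(nm) {
    p <- x[[nm]]
    if (!is.numeric(p) || length(p) < 1L) {
      stop("locus '", nm, "': frequencies must be a numeric vector")
    }
    if (is.null(names(p)) || anyDuplicated(names(p)) || any(!nzchar(names(p)))) {
      stop("locus '", nm, "': allele labels must be unique and non-empty")
    }
    if (any(!is.finite(p)) || any(p <= 0)) {
      stop("locus '", nm, "': all frequencies must be finite and > 0")
    }
    s <- sum(p)
    if (abs(s - 1) > 1e-6) {
      stop("locus '", nm, "': frequencies sum to ", format(s), ", not 1")
    }
    p / s
  })
  names(out) <- names(x)
  structure(out, class = "freq_set")
}

#' @export
print.freq_set <- function(x, ...) {
  na <- vapply(x, length, 0L)
  cat("Allele frequencies:", length(x), "loci,",
      paste(range(na), collapse = "-"), "alleles per locus\n")
  invisible(x)
}

#' Compute allele frequencies from a genotype table
#'
#' Per locus, the frequency of an allele is its count divided by twice the
#' number of non-missing individuals at that locus.
#'
#' @param table a [genotype_table()].
#' @return A [freq_set()].
#' @export
allele_frequencies <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  loci <- table$loci
  out <- lapply(seq_along(loci), function(l) {
    al <- c(table$a1[, l], table$a2[, l])
    al <- al[!is.na(al)]
    if (length(al) == 0L) {
      stop("locus '", loci[l], "': all genotypes missing, frequencies undefined")
    }
    tab <- table(al)
    p <- as.numeric(tab) / length(al)
    names(p) <- names(tab)
    p
  })
  names(out) <- loci
  freq_set(out)
}

#' Draw synthetic allele-frequency panels
#'
#' Per-locus frequencies are drawn from a symmetric Dirichlet distribution.
#' `concentration = Inf` is the equifrequent convention (all alleles at
#' `1/n_alleles`). The package default panel for simulation studies is
#' 18 loci with 8 alleles at concentration 2, a moderately diverse
#' microsatellite panel.
#'
#' @param n_loci number of loci (>= 1).
#' @param n_alleles alleles per locus (>= 2).
#' @param concentration symmetric Dirichlet concentration; `Inf` for
#'   equifrequent alleles.
#' @param seed optional integer seed.
#' @return A [freq_set()] with loci `L01`, `L02`, ... and allele labels
#'   `"1"`, `"2"`, ...
#' @examples
#' gen_frequencies(2, 4, concentration = Inf)
#' @export
gen_frequencies <- function(n_loci = 18L, n_alleles = 8L, concentration = 2,
                            seed = NULL) {
  stopifnot(n_loci >= 1L, n_alleles >= 2L, concentration > 0)
  labs <- as.character(seq_len(n_alleles))
  with_seed(seed, {
    out <- lapply(seq_len(n_loci), function(l) {
      p <- if (is.finite(concentration)) {
        g <- stats::rgamma(n_alleles, shape = concentration, rate = 1)
        # guard against an all-but-degenerate draw at tiny concentration
        g <- pmax(g, 1e-12)
        g / sum(g)
      } else {
        rep(1 / n_alleles, n_alleles)
      }
      names(p) <- labs
      p
    })
    names(out) <- sprintf("L%02d", seq_len(n_loci))
    freq_set(out)
  })
}

#' Read and write allele-frequency tables (CSV)
#'
#' Plain CSV with columns `locus, allele, freq`.
#'
#' @param path file path.
#' @return `read_frequency_csv()` returns a [freq_set()];
#'   `write_frequency_csv()` invisibly returns `path`.
#' @export
read_frequency_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character", "numeric"))
  if (!all(c("locus", "allele", "freq") %in% names(df))) {
    stop("frequency CSV needs columns locus, allele, freq")
  }
  out <- split(df, factor(df$locus, levels = unique(df$locus)))
  out <- lapply(out, function(d) stats::setNames(d$freq, d$allele))
  freq_set(out)
}

#' @rdname read_frequency_csv
#' @param freqs a [freq_set()].
#' @export
write_frequency_csv <- function(freqs, path) {
  stopifnot(inherits(freqs, "freq_set"))
  df <- do.call(rbind, lapply(names(freqs), function(l) {
    data.frame(locus = l, allele = names(freqs[[l]]), freq = as.numeric(freqs[[l]]))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
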