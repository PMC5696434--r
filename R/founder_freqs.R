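# Founder allele-frequency specifications.
#
# A frequency spec is the seed of every simulation: one frequency vector per
# microsatellite locus, from which founder genotypes are drawn in
# Hardy-Weinberg proportions.  Empirical per-locus frequencies for the focal
# mussel populations are unpublished; what is published is the per-locus
# expected heterozygosity, so the module can also synthesise frequency sets
# that hit a target He profile exactly.

#' Construct a per-locus allele-frequency specification
#'
#' @param loci list of numeric frequency vectors, one per locus.  Each vector
#'   gives the frequency of allele IDs `1..length(vector)` and must sum to 1
#'   (tolerance `1e-9`).  A fixed locus is a vector of length 1.
#' @param locus_names optional character vector of locus labels; defaults to
#'   the names of `loci` or `L1..Ln`.
#' @return an object of class `allele_freqs`: the validated list of frequency
#'   vectors with a `locus_names` attribute.
#' @examples
#' af <- allele_freqs(list(A = c(0.5, 0.5), B = 1))
#' expected_heterozygosity(af)
#' @export
allele_freqs <- function(loci, locus_names = NULL) {
  if (!is.list(loci) || length(loci) == 0L)
    stop("'loci' must be a non-empty list of frequency vectors")
  if (is.null(locus_names))
    locus_names <- if (!is.null(names(loci))) names(loci) else
      paste0("L", seq_along(loci))
  if (length(locus_names) != length(loci))
    stop("'locus_names' must match the number of loci")
  loci <- lapply(loci, as.numeric)
  for (l in seq_along(loci)) {
    f <- loci[[l]]
    if (length(f) < 1L || anyNA(f))
      stop("locus ", locus_names[l], ": at least one allele, no NA, required")
    if (any(f < 0))
      stop("locus ", locus_names[l], ": negative frequency")
    if (abs(sum(f) - 1) > 1e-9)
      stop("locus ", locus_names[l], ": frequencies sum to ", sum(f),
           ", not 1 (tolerance 1e-9)")
  }
  names(loci) <- locus_names
  structure(loci, locus_names = locus_names, class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("Allele-frequency spec:", length(x), "loci\n")
  he <- expected_heterozygosity(x)
  for (l in seq_along(x))
    cat(sprintf("  %-8s %d allele(s), He = %.3f\n",
                attr(x, "locus_names")[l], length(x[[l]]), he[l]))
  invisible(x)
}

n_loci <- function(freqs) length(freqs)

#' Per-locus expected heterozygosity of a frequency spec
#'
#' He at a locus with allele frequencies p is `1 - sum(p^2)`, the probability
#' that two gene copies drawn at random differ.  No small-sample correction is
#' applied: the spec describes population-level, not sample, frequencies.
#'
#' @param freqs an [allele_freqs] object.
#' @return named numeric vector of per-locus He.
#' @export
expected_heterozygosity <- function(freqs) {
  stopifnot(inherits(freqs, "allele_freqs"))
  vapply(unclass(freqs), function(p) 1 - sum(p^2), numeric(1))
}

# He of the symmetric-plus-dominant-allele parameterisation: one allele at
# frequency p, the remaining k-1 alleles sharing (1-p) equally.  Decreasing in
# p on [1/k, 1], from the maximum 1 - 1/k down to 0.
.he_dominant <- function(p, k) 1 - p^2 - if (k > 1) (1 - p)^2 / (k - 1) else 0

#' Synthesise allele frequencies matching a target heterozygosity profile
#'
#' Builds one frequency vector per locus whose expected heterozygosity matches
#' `target_he` to within `tol`.  The default method solves, by 1-D bisection,
#' for a "dominant" allele frequency p with the remaining alleles equally
#' frequent at (1-p)/(k-1); this is deterministic and exact to numerical
#' precision.  `method = "dirichlet"` instead draws symmetric Dirichlet(1)
#' vectors and keeps the first within tolerance, giving irregular frequency
#' profiles (uses the current RNG state; seed with [set.seed()]).
#'
#' @param target_he numeric vector of per-locus target He in `[0, 1)`.
#' @param n_alleles integer vector (recycled) of allele counts per locus.
#'   A target of 0 always yields a single fixed allele.
#' @param tol maximum tolerated |He - target| (default 0.005).
#' @param locus_names optional labels.
#' @param method `"bisection"` (default, deterministic) or `"dirichlet"`.
#' @param max_tries rejection-sampling cap for the Dirichlet method.
#' @return an [allele_freqs] object satisfying the tolerance contract.
#' @export
freqs_matching_he <- function(target_he, n_alleles = 6L, tol = 0.005,
                              locus_names = NULL,
                              method = c("bisection", "dirichlet"),
                              max_tries = 10000L) {
  method <- match.arg(method)
  n_alleles <- as.integer(rep_len(n_alleles, length(target_he)))
  if (is.null(locus_names))
    locus_names <- names(target_he) %||% paste0("L", seq_along(target_he))
  loci <- vector("list", length(target_he))
  for (l in seq_along(target_he)) {
    he <- target_he[l]; k <- n_alleles[l]
    if (he < 0 || he >= 1)
      stop("locus ", locus_names[l], ": target He must be in [0, 1)")
    if (he <= tol) { loci[[l]] <- 1; next }
    he_max <- 1 - 1 / k
    if (he > he_max + tol)
      stop("locus ", locus_names[l], ": target He ", he,
           " unreachable with ", k, " alleles (max ", round(he_max, 4), ")")
    he <- min(he, he_max)
    if (method == "bisection") {
      p <- stats::uniroot(function(p) .he_dominant(p, k) - he,
                          lower = 1 / k, upper = 1 - 1e-12,
                          tol = 1e-12)$root
      loci[[l]] <- c(p, rep((1 - p) / (k - 1), k - 1))
    } else {
      ok <- FALSE
      for (i in seq_len(max_tries)) {
        f <- stats::rgamma(k, 1); f <- f / sum(f)
        if (abs(1 - sum(f^2) - he) <= tol) { ok <- TRUE; break }
      }
      if (!ok)
        stop("locus ", locus_names[l],
             ": no Dirichlet draw within tolerance after ", max_tries,
             " tries; use method = \"bisection\"")
      loci[[l]] <- f
    }
  }
  out <- allele_freqs(loci, locus_names)
  err <- abs(expected_heterozygosity(out) - target_he)
  if (any(err > tol))  # defensive: the contract, not an expected path
    stop("internal error: He tolerance violated at locus ",
         locus_names[which.max(err)])
  out
}

#' Packaged founder profile
#'
#' `founder_profile()` returns the default founder frequency set used by the
#' simulator: six microsatellite loci (A112, A130, C4, C114, D102, R9) whose
#' expected heterozygosities (0.690, 0.804, 0.727, 0.489, 0, 0) reproduce the
#' published per-locus He of the mussel population sampled downstream of the
#' dam (site LG), the population the simulations are founded from.  The
#' per-allele frequencies themselves are synthetic -- the empirical ones are
#' unpublished -- built with [freqs_matching_he()]: a dominant allele plus
#' equally frequent minor alleles per polymorphic locus, and a single allele
#' at the two loci that were fixed at that site.
#'
#' @param profile profile name; only `"downstream-lg"` is shipped.
#' @return an [allele_freqs] object.
#' @export
founder_profile <- function(profile = "downstream-lg") {
  if (!identical(profile, "downstream-lg"))
    stop("unknown founder profile: ", profile)
  freqs_matching_he(
    target_he   = c(A112 = 0.690, A130 = 0.804, C4 = 0.727,
                    C114 = 0.489, D102 = 0, R9 = 0),
    n_alleles   = c(6L, 8L, 6L, 6L, 1L, 1L),
    tol         = 0.005
  )
}

#' Read / write a frequency table as CSV
#'
#' The on-disk format is a plain CSV with columns `locus`, `allele`,
#' `frequency`; allele IDs must be the consecutive integers `1..k` within
#' each locus.  Reading validates each locus and renormalises only when the
#' column sum deviates from 1 by less than `1e-6`; larger deviations are an
#' error, not a silent fix.
#'
#' @param path file path.
#' @return `read_allele_freqs()` returns an [allele_freqs] object;
#'   `write_allele_freqs()` returns `path` invisibly.
#' @export
read_allele_freqs <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus", "allele", "frequency")
  if (!all(need %in% names(tab)))
    stop("frequency CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) stop("frequency CSV is empty")
  if (anyNA(tab$frequency) || !is.numeric(tab$frequency))
    stop("malformed 'frequency' column")
  loci <- list()
  for (loc in unique(tab$locus)) {
    rows <- tab[tab$locus == loc, ]
    rows <- rows[order(rows$allele), ]
    if (!identical(as.integer(rows$allele), seq_len(nrow(rows))))
      stop("locus ", loc, ": allele IDs must be consecutive 1..k")
    f <- rows$frequency
    if (any(f < 0)) stop("locus ", loc, ": negative frequency")
    dev <- abs(sum(f) - 1)
    if (dev >= 1e-6)
      stop("locus ", loc, ": frequencies sum to ", sum(f),
           " (deviation ", signif(dev, 3), " >= 1e-6)")
    loci[[as.character(loc)]] <- f / sum(f)
  }
  allele_freqs(loci)
}

#' @rdname read_allele_freqs
#' @param freqs an [allele_freqs] object to serialise.
#' @export
write_allele_freqs <- function(freqs, path) {
  stopifnot(inherits(freqs, "allele_freqs"))
  tab <- do.call(rbind, lapply(seq_along(freqs), function(l) {
    data.frame(locus     = attr(freqs, "locus_names")[l],
               allele    = seq_along(freqs[[l]]),
               frequency = freqs[[l]])
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
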