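#' Allele combination acronym at the Ppd-A1 / Ppd-B1 photoperiod loci
#'
#' Maps the allele carried at each of the two photoperiod-sensitivity loci of
#' durum wheat to the standard two/three-letter acronym for the joint
#' combination.  `Ppd-A1` has three alleles: the photoperiod-sensitive wild
#' type `Ppd-A1b` and two insensitivity alleles, `GS100-Ppd-A1a` and
#' `GS105-Ppd-A1a`.  `Ppd-B1` has the sensitive `Ppd-B1b` and the insensitive
#' `Ppd-B1a`.
#'
#' @param ppd_a1 character vector of `Ppd-A1` allele names
#'   (`"GS100-Ppd-A1a"`, `"GS105-Ppd-A1a"` or `"Ppd-A1b"`).
#' @param ppd_b1 character vector of `Ppd-B1` allele names
#'   (`"Ppd-B1a"` or `"Ppd-B1b"`).
#' @return character vector of acronyms among
#'   `"I0I", "I0S", "I5I", "I5S", "SI", "SS"`.
#' @examples
#' allele_combination("GS100-Ppd-A1a", "Ppd-B1a")  # "I0I"
#' allele_combination("Ppd-A1b", "Ppd-B1b")        # "SS"
#' @export
allele_combination <- function(ppd_a1, ppd_b1) {
  map <- c(
    "GS100-Ppd-A1a|Ppd-B1a" = "I0I",
    "GS100-Ppd-A1a|Ppd-B1b" = "I0S",
    "GS105-Ppd-A1a|Ppd-B1a" = "I5I",
    "GS105-Ppd-A1a|Ppd-B1b" = "I5S",
    "Ppd-A1b|Ppd-B1a"       = "SI",
    "Ppd-A1b|Ppd-B1b"       = "SS")
  key <- paste(ppd_a1, ppd_b1, sep = "|")
  ac <- unname(map[key])
  if (anyNA(ac)) {
    bad <- unique(key[is.na(ac)])
    stop("unknown Ppd-A1/Ppd-B1 allele pair(s): ", paste(bad, collapse = ", "))
  }
  ac
}

#' Validate and enrich a genotype metadata table
#'
#' Adds the `allele_combination` acronym and flags combinations represented by
#' fewer than two genotypes as `excluded` (a singleton combination carries no
#' within-combination information and is discarded from group-level analyses).
#'
#' @param genotypes data frame with columns `genotype`, `ppd_a1`, `ppd_b1`.
#' @return the input with added columns `allele_combination` (character) and
#'   `excluded` (logical).
#' @export
genotype_meta <- function(genotypes) {
  stopifnot(is.data.frame(genotypes))
  need <- c("genotype", "ppd_a1", "ppd_b1")
  miss <- setdiff(need, names(genotypes))
  if (length(miss))
    stop("genotype table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(genotypes$genotype))
    stop("duplicated genotype ids in genotype table")
  genotypes$genotype <- as.character(genotypes$genotype)
  genotypes$allele_combination <-
    allele_combination(genotypes$ppd_a1, genotypes$ppd_b1)
  n_ac <- table(genotypes$allele_combination)
  genotypes$excluded <- n_ac[genotypes$allele_combination] < 2L
  genotypes$excluded <- as.logical(genotypes$excluded)
  genotypes
}

#' Default genotype roster
#'
#' The 24-genotype roster used throughout the synthetic trial: 5 SS, 5 SI,
#' 4 I5S, 6 I5I, 3 I0I genotypes plus one singleton I0S genotype that is
#' flagged `excluded` (combinations with fewer than two members are discarded
#' from the analyses).
#'
#' @return genotype metadata data frame (see [genotype_meta()]).
#' @export
default_genotypes <- function() {
  a1 <- c(rep("Ppd-A1b", 10), rep("GS105-Ppd-A1a", 10),
          rep("GS100-Ppd-A1a", 4))
  b1 <- c(rep("Ppd-B1b", 5), rep("Ppd-B1a", 5),   # SS, SI
          rep("Ppd-B1b", 4), rep("Ppd-B1a", 6),   # I5S, I5I
          "Ppd-B1b", rep("Ppd-B1a", 3))           # I0S (singleton), I0I
  genotype_meta(data.frame(
    genotype = sprintf("G%02d", seq_along(a1)),
    ppd_a1 = a1, ppd_b1 = b1,
    stringsAsFactors = FALSE))
}

#' Read a genotype metadata CSV
#'
#' Expects columns `genotype`, `ppd_a1`, `ppd_b1` with allele names written
#' exactly as in [allele_combination()].
#'
#' @param path CSV file path.
#' @return genotype metadata data frame (see [genotype_meta()]).
#' @export
read_genotype_table <- function(path) {
  genotype_meta(utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = "character"))
}

#' Write a genotype metadata CSV
#' @param genotypes genotype metadata data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  utils::write.csv(genotypes[c("genotype", "ppd_a1", "ppd_b1")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
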