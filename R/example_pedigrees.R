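#' Standard test pedigrees
#'
#' Convenience constructors for the pedigree structures used throughout the
#' documentation and tests: a parent-offspring trio, a nuclear family with a
#' configurable number of full siblings of the index, and a three-generation
#' family (index, parents, four grandparents, and aunts/uncles on each side).
#' These are the package's own documented structures; published analyses of
#' this kind typically use broadly similar extended families.
#'
#' @param n_sibs Number of full siblings of the index in `ped_nuclear()`.
#' @param n_aunts_uncles Number of siblings of each parent in
#'   `ped_three_generation()`.
#' @return A [pedigree()] with the index individual first.
#' @examples
#' ped_trio()
#' nrow(ped_nuclear(n_sibs = 3))          # 6 individuals
#' nrow(ped_three_generation())           # 9 individuals
#' @export
ped_trio <- function() {
  pedigree(id = c("index", "father", "mother"),
           father_id = c("father", NA, NA),
           mother_id = c("mother", NA, NA),
           sex = c("male", "male", "female"),
           index = "index", famid = "TRIO")
}

#' @rdname ped_trio
#' @export
ped_nuclear <- function(n_sibs = 2L) {
  stopifnot(n_sibs >= 0L)
  sibs <- if (n_sibs > 0L) paste0("sib", seq_len(n_sibs)) else character()
  ids <- c("index", "father", "mother", sibs)
  pedigree(id = ids,
           father_id = c("father", NA, NA, rep("father", n_sibs)),
           mother_id = c("mother", NA, NA, rep("mother", n_sibs)),
           sex = c("female", "male", "female",
                   rep(c("male", "female"), length.out = n_sibs)),
           index = "index", famid = "NUCLEAR")
}

#' @rdname ped_trio
#' @export
ped_three_generation <- function(n_aunts_uncles = 1L) {
  stopifnot(n_aunts_uncles >= 0L)
  pu <- if (n_aunts_uncles > 0L) paste0("pat_au", seq_len(n_aunts_uncles)) else character()
  mu <- if (n_aunts_uncles > 0L) paste0("mat_au", seq_len(n_aunts_uncles)) else character()
  ids <- c("index", "father", "mother", "pgf", "pgm", "mgf", "mgm", pu, mu)
  fa <- c("father", "pgf", "mgf", NA, NA, NA, NA,
          rep("pgf", length(pu)), rep("mgf", length(mu)))
  mo <- c("mother", "pgm", "mgm", NA, NA, NA, NA,
          rep("pgm", length(pu)), rep("mgm", length(mu)))
  sex <- c("male", "male", "female", "male", "female", "male", "female",
           rep(c("male", "female"), length.out = length(pu)),
           rep(c("female", "male"), length.out = length(mu)))
  pedigree(id = ids, father_id = fa, mother_id = mo, sex = sex,
           index = "index", famid = "THREEGEN")
}
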