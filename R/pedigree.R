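#' Construct a pedigree
#'
#' A pedigree is an ordered set of individuals with optional parent links and
#' sexes.  One individual is designated the index individual (consultand) —
#' the person whose disease risk is being predicted — and is always stored in
#' position 1; all vector and matrix orderings in the package follow this
#' convention.
#'
#' @param id Character vector of individual identifiers (unique).
#' @param father_id,mother_id Character vectors of parent identifiers;
#'   `NA` or `"0"` means the parent is not in the pedigree (founder link).
#' @param sex Sex codes: `"male"`, `"female"`, or `"unknown"` (also accepts
#'   PED numeric codes 1/2/0).
#' @param index Identifier of the index individual.  Exactly one individual
#'   must be the index.
#' @param famid Family identifier used when writing PED files.
#'
#' @return An object of class `pedigree`: a data frame with columns `id`,
#'   `father_id`, `mother_id`, `sex`, `is_index`, the index individual first,
#'   remaining individuals sorted so that parents precede their children.
#'   The attribute `relmat`, when present, overrides the recursive
#'   relationship-matrix computation (used by [marginalize_sex()]).
#'
#' @examples
#' trio <- pedigree(id = c("child", "dad", "mom"),
#'                  father_id = c("dad", NA, NA),
#'                  mother_id = c("mom", NA, NA),
#'                  sex = c("male", "male", "female"),
#'                  index = "child")
#' relationship_matrix(trio)
#' @export
pedigree <- function(id, father_id = NA, mother_id = NA,
                     sex = "unknown", index = id[1], famid = "FAM1") {
  id <- as.character(id)
  n <- length(id)
  if (n < 1L) stop("a pedigree needs at least one individual")
  if (anyDuplicated(id)) stop("duplicate individual ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  norm_parent <- function(p) {
    p <- as.character(rep_len(p, n))
    p[is.na(p) | p == "0" | p == ""] <- NA_character_
    p
  }
  father_id <- norm_parent(father_id)
  mother_id <- norm_parent(mother_id)
  sex <- normalize_sex(rep_len(sex, n))

  for (col in list(father = father_id, mother = mother_id)) {
    bad <- !is.na(col) & !(col %in% id)
    if (any(bad))
      stop("unresolved parent id(s): ", paste(unique(col[bad]), collapse = ", "),
           " (parents must be pedigree members or missing)")
  }
  if (any(!is.na(father_id) & father_id == id) ||
      any(!is.na(mother_id) & mother_id == id))
    stop("an individual cannot be its own parent")
  if (length(index) != 1L || !(index %in% id))
    stop("`index` must name exactly one pedigree member")

  ped <- data.frame(id = id, father_id = father_id, mother_id = mother_id,
                    sex = sex, is_index = id == index,
                    stringsAsFactors = FALSE)
  ped <- ped[order_pedigree(ped), , drop = FALSE]
  rownames(ped) <- NULL
  structure(ped, class = c("pedigree", "data.frame"), famid = famid)
}

normalize_sex <- function(sex) {
  sex <- as.character(sex)
  out <- c("1" = "male", "2" = "female", "0" = "unknown",
           male = "male", female = "female", unknown = "unknown",
           M = "male", F = "female", m = "male", f = "female")[sex]
  if (anyNA(out)) stop("unrecognized sex code(s): ",
                       paste(unique(sex[is.na(out)]), collapse = ", "))
  unname(out)
}

# Topological order with the index individual first among a parents-before-
# children ordering (founders first).  Detects cyclic ancestry.
order_pedigree <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  depth <- rep(NA_integer_, n)
  assign_depth <- function(i, seen) {
    if (!is.na(depth[i])) return(depth[i])
    if (seen[i]) stop("cyclic ancestry detected at individual '", ped$id[i], "'")
    seen[i] <- TRUE
    d <- 0L
    for (p in c(fa[i], mo[i])) if (!is.na(p))
      d <- max(d, assign_depth(p, seen) + 1L)
    depth[i] <<- d
    d
  }
  for (i in seq_len(n)) assign_depth(i, logical(n))
  topo <- order(depth, seq_len(n))
  idx <- which(ped$is_index)
  if (length(idx) != 1L) stop("exactly one index individual is required")
  c(idx, setdiff(topo, idx))
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree '%s' with %d individual(s); index: %s\n",
              attr(x, "famid"), nrow(x), x$id[x$is_index]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a pedigree from a PED/FAM-style text file
#'
#' Expects whitespace-delimited columns `FID IID PAT MAT SEX [PROBAND ...]`,
#' with `"0"` denoting a missing parent and SEX coded 1 = male, 2 = female,
#' 0 = unknown.  The index individual is taken from a sixth column (any
#' nonzero value flags the proband) unless `index` is supplied explicitly.
#'
#' @param path Path to the PED file.
#' @param index Optional id of the index individual, overriding the proband
#'   column.
#' @param famid Optional family id to select when the file contains several
#'   families; defaults to the first family in the file.
#' @return A [pedigree()].
#' @export
read_ped <- function(path, index = NULL, famid = NULL) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) < 5L)
    stop("PED file must have at least 5 columns (FID IID PAT MAT SEX): ", path)
  if (is.null(famid)) famid <- tab[[1L]][1L]
  tab <- tab[tab[[1L]] == famid, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for family '", famid, "' in ", path)

  if (is.null(index)) {
    if (ncol(tab) >= 6L) {
      flag <- tab[[6L]] != "0"
      if (sum(flag) != 1L)
        stop("PED file must flag exactly one proband in column 6 ",
             "(found ", sum(flag), "); pass `index` to override")
      index <- tab[[2L]][flag]
    } else {
      stop("no proband column in ", path, "; pass `index` explicitly")
    }
  }
  pedigree(id = tab[[2L]], father_id = tab[[3L]], mother_id = tab[[4L]],
           sex = tab[[5L]], index = index, famid = famid)
}

#' Write a pedigree as a PED/FAM-style text file
#'
#' Emits the same dialect [read_ped()] accepts: `FID IID PAT MAT SEX PROBAND`,
#' with an optional seventh phenotype column (1 = unaffected, 2 = affected)
#' when `status` is supplied.
#'
#' @param ped A [pedigree()].
#' @param path Output file path.
#' @param status Optional 0/1 affection-status vector in pedigree order.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, status = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  sexcode <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  out <- data.frame(attr(ped, "famid"), ped$id,
                    ifelse(is.na(ped$father_id), "0", ped$father_id),
                    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    sexcode, ifelse(ped$is_index, "1", "0"))
  if (!is.null(status)) {
    stopifnot(length(status) == nrow(ped))
    out <- cbind(out, as.integer(status) + 1L)
  }
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Additive genetic relationship matrix of a pedigree
#'
#' Computes the numerator relationship matrix A by the tabular method:
#' founders get 1 on the diagonal and 0 with other founders; for a
#' non-founder `i` with parents `p` and `m`, `A[i, j] = (A[p, j] + A[m, j]) / 2`
#' for `j != i` (a missing parent contributes 0) and
#' `A[i, i] = 1 + A[p, m] / 2`.  Entries are twice the kinship coefficient:
#' 0.5 for parent-offspring and full siblings, 0.25 for grandparent-
#' grandchild, 0.125 for first cousins.
#'
#' @param ped A [pedigree()].
#' @return A symmetric n x n matrix with the pedigree ids as dimnames.
#'   Diagonal entries exceed 1 only for inbred individuals, which trigger a
#'   warning (the model assumes outbred families).
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  pre <- attr(ped, "relmat")
  if (!is.null(pre)) return(pre)

  # tabular method needs parents before children; individual 1 is the index,
  # so compute in topological order and permute back
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  depth <- integer(n)
  repeat {
    d <- pmax(ifelse(is.na(fa), 0L, depth[fa] + 1L),
              ifelse(is.na(mo), 0L, depth[mo] + 1L))
    if (identical(d, depth)) break
    depth <- d
  }
  ord <- order(depth, seq_len(n))
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in ord) {
    p <- fa[i]; m <- mo[i]
    apm <- if (!is.na(p) && !is.na(m)) A[p, m] else 0
    A[i, i] <- 1 + 0.5 * apm
    for (j in ord) {
      if (j == i) break  # ord visits ancestors of i before i
      aij <- 0.5 * ((if (!is.na(p)) A[p, j] else 0) +
                    (if (!is.na(m)) A[m, j] else 0))
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  if (any(diag(A) > 1 + 1e-12))
    warning("pedigree contains inbreeding (diagonal of A exceeds 1); ",
            "the liability model assumes outbred families")
  A
}

#' Remove individuals of a non-applicable sex from a pedigree
#'
#' For sex-limited diseases (e.g. ovarian or prostate cancer) individuals of
#' the non-applicable sex have no observable phenotype.  Marginalizing them
#' out of the joint liability normal is mathematically equivalent to
#' removing them from the model, so this returns a reduced pedigree whose
#' stored relationship matrix is the corresponding submatrix of the full
#' pedigree's A (parent links to removed individuals are cut, which is why
#' the submatrix is carried along rather than recomputed).
#'
#' Individuals of unknown sex are retained.  If the index individual itself
#' is of the non-applicable sex, an error instructs the caller to flip the
#' sexes of the whole pedigree first (the standard device for evaluating a
#' sex-limited disease on a pedigree drawn with the other sex as index).
#'
#' @param ped A [pedigree()].
#' @param applicable_sex `"male"` or `"female"`: the sex for which the
#'   disease is defined.  `"both"` returns the pedigree unchanged.
#' @return A [pedigree()] containing the index and all relatives of the
#'   applicable (or unknown) sex.
#' @seealso [flip_sexes()]
#' @export
marginalize_sex <- function(ped, applicable_sex = c("both", "male", "female")) {
  stopifnot(inherits(ped, "pedigree"))
  applicable_sex <- match.arg(applicable_sex)
  if (applicable_sex == "both") return(ped)
  if (ped$sex[ped$is_index] != applicable_sex && ped$sex[ped$is_index] != "unknown")
    stop("the index individual's sex is not applicable for this disease; ",
         "flip the pedigree's sexes first (see flip_sexes())")
  keep <- ped$sex == applicable_sex | ped$sex == "unknown" | ped$is_index
  A <- relationship_matrix(ped)[keep, keep, drop = FALSE]
  out <- ped[keep, , drop = FALSE]
  # cut links to removed parents
  out$father_id[!(out$father_id %in% out$id)] <- NA_character_
  out$mother_id[!(out$mother_id %in% out$id)] <- NA_character_
  rownames(out) <- NULL
  structure(out, class = c("pedigree", "data.frame"),
            famid = attr(ped, "famid"), relmat = A)
}

#' Swap the sexes of every pedigree member
#'
#' @param ped A [pedigree()].
#' @return The pedigree with male and female labels exchanged.
#' @export
flip_sexes <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped$sex <- c(male = "female", female = "male", unknown = "unknown")[ped$sex]
  ped
}

#' Enumerate all disease-status patterns of a pedigree
#'
#' Lists every vector of lifetime disease statuses (1 = affected) for the
#' pedigree members, in binary-counting order with the index individual as
#' the lowest-order bit.  There are `2^n` patterns for `n` individuals.
#'
#' @param ped A [pedigree()] (or an integer count of individuals).
#' @param max_n Size cap; enumeration above it is refused (each pattern
#'   costs one multivariate-normal integral downstream, so `2^n` grows
#'   quickly past desk scale).  Default 16.
#' @return A `2^n` x `n` 0/1 integer matrix, one pattern per row, columns
#'   in pedigree order (index first).
#' @export
enumerate_patterns <- function(ped, max_n = 16L) {
  n <- if (inherits(ped, "pedigree")) nrow(ped) else as.integer(ped)
  if (n > max_n)
    stop("pedigree of size ", n, " exceeds the enumeration cap of ", max_n,
         " (2^n patterns each requiring an MVN integral); consider the ",
         "restricted model or a smaller pedigree")
  m <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  if (inherits(ped, "pedigree")) colnames(m) <- ped$id
  m
}
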