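#' Create a pedigree object
#'
#' A pedigree is a three-column table of individual, sire and dam identifiers.
#' Unknown parents are `NA`. On construction the table is validated (unique
#' ids, no individual its own ancestor), parents that never appear in the
#' `id` column are auto-promoted to founder rows, and rows are topologically
#' sorted so that parents always precede their offspring.
#'
#' @param id,sire,dam character vectors of equal length; `NA` (or `""`) marks
#'   an unknown parent.
#' @return A `data.frame` of class `"colony_pedigree"` with columns
#'   `id`, `sire`, `dam`, sorted parents-first.
#' @examples
#' ped <- pedigree(id = c("o", "s", "d"), sire = c("s", NA, NA),
#'                 dam = c("d", NA, NA))
#' pedigree_stats(ped)
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  sire[!is.na(sire) & sire == ""] <- NA_character_
  dam[!is.na(dam) & dam == ""] <- NA_character_
  if (anyDuplicated(id)) {
    cqg_stop(paste0("duplicate individual id(s): ",
                    paste(unique(id[duplicated(id)]), collapse = ", ")),
             "colonyQG_duplicate_record")
  }
  # auto-promote parents never listed as individuals to founders
  extra <- setdiff(c(sire, dam), c(id, NA))
  if (length(extra)) {
    id <- c(id, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
  }
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  ped <- topo_sort_pedigree(ped)
  class(ped) <- c("colony_pedigree", "data.frame")
  ped
}

# Kahn's algorithm on parent -> offspring edges computes each individual's
# depth; the canonical order is (depth, id), which is a valid topological
# order and independent of the input row order. Reports one cycle on failure.
topo_sort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- idx[ped$sire]; di <- idx[ped$dam]  # NA where unknown
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  depth <- integer(n)
  queue <- which(indeg == 0L)
  n_done <- length(queue)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (k in kids[[v]]) {
      depth[k] <- max(depth[k], depth[v] + 1L)
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) {
        queue <- c(queue, k)
        n_done <- n_done + 1L
      }
    }
  }
  if (n_done < n) {
    cyc <- find_one_cycle(ped, which(indeg > 0L))
    cqg_stop(paste0("pedigree contains a cycle: ",
                    paste(cyc, collapse = " -> ")),
             "colonyQG_cyclic_pedigree")
  }
  ped <- ped[order(depth, ped$id), , drop = FALSE]
  rownames(ped) <- NULL
  ped
}

find_one_cycle <- function(ped, in_cycle_idx) {
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  start <- in_cycle_idx[[1]]
  seen <- integer(0)
  v <- start
  repeat {
    seen <- c(seen, v)
    p <- c(idx[ped$sire[v]], idx[ped$dam[v]])
    p <- p[!is.na(p) & p %in% in_cycle_idx]
    v <- p[[1]]
    if (v %in% seen) {
      path <- c(seen[which(seen == v):length(seen)], v)
      return(ped$id[path])
    }
  }
}

#' Read a pedigree from a three-column CSV file
#'
#' Expects columns `id`, `sire`, `dam` (header required); empty fields mark
#' unknown parents. Rows may be in any order: the result is topologically
#' sorted. Cycles and duplicate ids raise classed errors.
#'
#' @param path path to a CSV file.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- read.csv(path, colClasses = "character", na.strings = c("", "NA"))
  if (ncol(df) < 3) cqg_stop("pedigree file must have 3 columns (id, sire, dam)",
                             "colonyQG_bad_file")
  pedigree(df[[1]], df[[2]], df[[3]])
}

#' Write a pedigree to CSV
#'
#' @param ped a [pedigree()] object.
#' @param path output path; unknown parents are written as empty fields.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Prune a pedigree to phenotyped individuals and their ancestors
#'
#' Restricts the pedigree to the individuals that carry phenotypes plus every
#' ancestor of those individuals; all other individuals are uninformative for
#' an animal model and are dropped. Phenotyped ids absent from the pedigree
#' are retained as founders with a warning.
#'
#' @param ped a [pedigree()] object.
#' @param phenotyped_ids character vector of phenotyped individual ids.
#' @return A pruned [pedigree()] object.
#' @export
prune_pedigree <- function(ped, phenotyped_ids) {
  phenotyped_ids <- unique(as.character(phenotyped_ids))
  if (!length(phenotyped_ids)) {
    cqg_stop("phenotyped_ids must be non-empty", "colonyQG_invalid_argument")
  }
  missing <- setdiff(phenotyped_ids, ped$id)
  if (length(missing)) {
    cqg_warn(paste0(length(missing), " phenotyped id(s) absent from pedigree; ",
                    "retained as founders"), "colonyQG_unknown_phenotyped")
  }
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  keep <- logical(nrow(ped))
  # walk ancestors from the phenotyped set (pedigree is parents-first, so a
  # reverse sweep closes the ancestor set in one pass)
  keep[idx[intersect(phenotyped_ids, ped$id)]] <- TRUE
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      for (p in c(ped$sire[i], ped$dam[i])) {
        if (!is.na(p)) keep[idx[[p]]] <- TRUE
      }
    }
  }
  kept <- ped[keep, , drop = FALSE]
  pedigree(id = c(kept$id, missing),
           sire = c(kept$sire, rep(NA_character_, length(missing))),
           dam = c(kept$dam, rep(NA_character_, length(missing))))
}

#' Pedigree summary statistics
#'
#' @param ped a [pedigree()] object.
#' @return A list with `size` (number of individuals), `max_depth` (longest
#'   founder-to-descendant chain of parent-offspring links; founders have
#'   depth 0), `n_paternities` (individuals with known sire) and
#'   `n_maternities` (individuals with known dam).
#' @export
pedigree_stats <- function(ped) {
  stopifnot(inherits(ped, "colony_pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(p)) d <- max(d, depth[idx[[p]]] + 1L)
    }
    depth[i] <- d
  }
  list(size = n,
       max_depth = if (n) max(depth) else 0L,
       n_paternities = sum(!is.na(ped$sire)),
       n_maternities = sum(!is.na(ped$dam)))
}

#' Generalized Cholesky factor of the additive relationship matrix
#'
#' Computes the sparse lower-triangular factor `L` with `A = L L'` implied by
#' the pedigree (the decomposition `A = T D T'` with `T` from the
#' parent-averaging recursion and `D` the Mendelian-sampling variances), plus
#' each individual's inbreeding coefficient `F`. Founders are assumed
#' non-inbred; inbreeding of descendants follows from the factor itself.
#'
#' @param ped a [pedigree()] object.
#' @return list with `L` (sparse [Matrix::sparseMatrix()] in pedigree order,
#'   dimnames = ids), `F` (named inbreeding coefficients) and `D`
#'   (Mendelian-sampling variances).
#' @export
pedigree_factor <- function(ped) {
  stopifnot(inherits(ped, "colony_pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  rows <- vector("list", n)     # sparse rows of L as named numeric vectors
  Fi <- numeric(n)
  Di <- numeric(n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    si <- if (is.na(s)) NA_integer_ else idx[[s]]
    di <- if (is.na(d)) NA_integer_ else idx[[d]]
    if (is.na(si) && is.na(di)) {
      Fi[i] <- 0; Di[i] <- 1
      rows[[i]] <- c(structure(1, names = as.character(i)))
    } else if (is.na(si) || is.na(di)) {
      pi <- if (is.na(si)) di else si
      Fi[i] <- 0
      Di[i] <- 0.75 - 0.25 * Fi[pi]
      r <- 0.5 * rows[[pi]]
      r[as.character(i)] <- sqrt(Di[i])
      rows[[i]] <- r
    } else {
      # F_i = kinship(sire, dam) = A_sd / 2 = <L_s, L_d> / 2
      common <- intersect(names(rows[[si]]), names(rows[[di]]))
      Asd <- if (length(common)) sum(rows[[si]][common] * rows[[di]][common]) else 0
      Fi[i] <- 0.5 * Asd
      Di[i] <- 0.5 - 0.25 * (Fi[si] + Fi[di])
      r <- 0.5 * rows[[si]]
      rd <- 0.5 * rows[[di]]
      both <- intersect(names(r), names(rd))
      r[both] <- r[both] + rd[both]
      only_d <- setdiff(names(rd), both)
      r[only_d] <- rd[only_d]
      r[as.character(i)] <- sqrt(Di[i])
      rows[[i]] <- r
    }
  }
  ii <- rep.int(seq_len(n), lengths(rows))
  jj <- as.integer(unlist(lapply(rows, names), use.names = FALSE))
  xx <- unlist(rows, use.names = FALSE)
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$id, ped$id))
  names(Fi) <- ped$id
  list(L = L, F = Fi, D = Di)
}

#' Build the additive (numerator) relationship matrix A
#'
#' Uses the tabular method: for individuals sorted parents-first,
#' `A[i,i] = 1 + A[s,d]/2` and `A[i,j] = (A[j,s] + A[j,d])/2` for earlier `j`,
#' an unknown parent contributing 0. The diagonal is `1 + F`. Pedigrees above
#' `sparse_threshold` individuals are factored instead (`A = L L'`) and
#' returned sparse; the numerical contract is identical.
#'
#' @param ped a [pedigree()] object (re-sorted internally if needed).
#' @param sparse_threshold pedigree size above which a sparse representation
#'   is returned (default 3000).
#' @return A symmetric matrix with dimnames = pedigree ids: base `matrix` for
#'   small pedigrees, [Matrix::dsCMatrix-class] above the threshold.
#' @export
build_a_matrix <- function(ped, sparse_threshold = 3000) {
  if (!inherits(ped, "colony_pedigree")) ped <- pedigree(ped$id, ped$sire, ped$dam)
  n <- nrow(ped)
  if (n > sparse_threshold) {
    L <- pedigree_factor(ped)$L
    return(Matrix::forceSymmetric(Matrix::tcrossprod(L)))
  }
  idx <- seq_len(n); names(idx) <- ped$id
  si <- idx[ped$sire]; di <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    Asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * Asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else numeric(i - 1L)
      ad_ <- if (!is.na(d)) A[j, d] else numeric(i - 1L)
      v <- 0.5 * (as_ + ad_)
      A[j, i] <- v
      A[i, j] <- v
    }
  }
  A
}

#' Export a relationship matrix in Matrix Market format
#'
#' @param A matrix from [build_a_matrix()].
#' @param path output `.mtx` path; ids are written alongside as
#'   `<path>.ids.txt` (one id per line).
#' @return `path`, invisibly.
#' @export
write_a_matrix <- function(A, path) {
  M <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(M, path)
  writeLines(rownames(A), paste0(path, ".ids.txt"))
  invisible(path)
}

#' @export
print.colony_pedigree <- function(x, ...) {
  st <- pedigree_stats(x)
  cat(sprintf("<colony_pedigree> %d individuals, max depth %d, %d paternities, %d maternities\n",
              st$size, st$max_depth, st$n_paternities, st$n_maternities))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
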