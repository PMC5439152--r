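# Pedigree, genotype, phase and dosage containers and their file dialects.
#
# All files are plain whitespace-delimited text with the individual id in the
# first column (the AlphaImpute convention).  The unknown-parent token is "0".

#' Construct a pedigree
#'
#' A pedigree is a tibble with columns `id`, `sire`, `dam` (character; `NA`
#' for unknown parents) plus integer columns `sire_idx` and `dam_idx` giving
#' the row of each known parent.  Rows are topologically sorted so that every
#' known parent precedes its offspring.  Individuals referenced only as
#' parents are appended as founders.
#'
#' @param id,sire,dam character vectors of equal length; the literal token
#'   `"0"` (or `NA`) marks an unknown parent.
#' @return a `pedigree` object (tibble subclass).
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (anyDuplicated(id)) {
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sire[sire %in% "0"] <- NA_character_
  dam[dam %in% "0"] <- NA_character_
  # append parents that never occur as individuals, as founders
  extra <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(extra)) {
    id <- c(id, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
  }
  ord <- topo_order(id, sire, dam)
  ped <- tibble::tibble(id = id[ord], sire = sire[ord], dam = dam[ord])
  ped$sire_idx <- match(ped$sire, ped$id)
  ped$dam_idx <- match(ped$dam, ped$id)
  class(ped) <- c("pedigree", class(ped))
  ped
}

# Kahn's algorithm; names one individual on a cycle on failure.
topo_order <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
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
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    out <- c(out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    bad <- setdiff(seq_len(n), out)[1]
    stop("pedigree cycle detected involving individual '", id[bad], "'")
  }
  out
}

#' Read a pedigree file
#'
#' Whitespace-delimited rows `id sire dam`; `"0"` codes an unknown parent.
#'
#' @param path path to the pedigree file.
#' @return a [pedigree()] in topological order.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 3) stop("pedigree file needs 3 columns: id sire dam")
  pedigree(tab[[1]], tab[[2]], tab[[3]])
}

#' Read a genotype file aligned to a pedigree
#'
#' Rows are `id g1 ... gM` with genotypes coded 0 (reference homozygote),
#' 1 (heterozygote), 2 (alternative homozygote) or 9 (missing).  Individuals
#' absent from the file get all-9 rows.
#'
#' @param path path to the genotype file.
#' @param ped a [pedigree()].
#' @return integer matrix, rows in pedigree order, rownames = ids.
#' @export
read_genotypes <- function(path, ped) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  widths <- lengths(parts)
  if (length(unique(widths)) > 1) {
    stop("ragged genotype file: row ", which(widths != widths[1])[1],
         " has ", widths[which(widths != widths[1])[1]] - 1L, " markers")
  }
  M <- widths[1] - 1L
  ids <- vapply(parts, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.integer(p[-1]), integer(M))
  )
  vals <- matrix(vals, nrow = M) # one column per file row
  bad <- which(!(vals %in% c(0L, 1L, 2L, 9L)) | is.na(vals))
  if (length(bad)) {
    b <- bad[1] - 1L
    stop(sprintf("invalid genotype code at row %d, marker %d",
                 b %/% M + 1L, b %% M + 1L))
  }
  G <- matrix(MISSING, nrow = nrow(ped), ncol = M,
              dimnames = list(ped$id, NULL))
  keep <- ids %in% ped$id
  G[ids[keep], ] <- t(vals[, keep, drop = FALSE])
  storage.mode(G) <- "integer"
  G
}

#' Read a marker map
#'
#' Rows `marker_id chrom position_cM`.  If no map is supplied elsewhere in the
#' package, markers are placed at 1 cM intervals.
#'
#' @param path path to the map file.
#' @return tibble with columns `marker`, `chrom`, `pos_cM`.
#' @export
read_marker_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("marker", "chrom", "pos_cM"),
                           colClasses = c("character", "character", "numeric"))
  if (is.unsorted(tab$pos_cM)) stop("map positions must be non-decreasing")
  tibble::as_tibble(tab)
}

#' Default marker map: 1 cM spacing
#' @param M marker count.
#' @return tibble as in [read_marker_map()].
#' @export
default_marker_map <- function(M) {
  tibble::tibble(marker = paste0("m", seq_len(M)),
                 chrom = "1", pos_cM = as.numeric(seq_len(M) - 1L))
}

#' Read a phase file
#'
#' Two rows per individual (`id a1 ... aM`, alleles 0/1/9); the first row is
#' the gamete inherited from the sire, the second from the dam.
#'
#' @param path path to the phase file.
#' @param ped a [pedigree()].
#' @return integer matrix with `2 * nrow(ped)` rows; rows `2i - 1`, `2i`
#'   are individual i's paternal and maternal gametes.
#' @export
read_phase <- function(path, ped) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  M <- lengths(parts)[1] - 1L
  ids <- vapply(parts, `[[`, character(1), 1L)
  vals <- t(vapply(parts, function(p) as.integer(p[-1]), integer(M)))
  P <- matrix(MISSING, nrow = 2L * nrow(ped), ncol = M)
  rownames(P) <- paste(rep(ped$id, each = 2), c("pat", "mat"), sep = ".")
  for (i in seq_len(nrow(ped))) {
    rows <- which(ids == ped$id[i])
    if (length(rows) == 2) {
      P[2L * i - 1L, ] <- vals[rows[1], ]
      P[2L * i, ] <- vals[rows[2], ]
    }
  }
  storage.mode(P) <- "integer"
  P
}

#' Read a dosage file
#' @param path path to the dosage file.
#' @param ped a [pedigree()].
#' @return numeric matrix aligned to the pedigree (NA rows when absent).
#' @export
read_dosages <- function(path, ped) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  ids <- tab[[1]]
  vals <- apply(as.matrix(tab[, -1, drop = FALSE]), c(1, 2), as.numeric)
  D <- matrix(NA_real_, nrow = nrow(ped), ncol = ncol(vals),
              dimnames = list(ped$id, NULL))
  D[ids[ids %in% ped$id], ] <- vals[ids %in% ped$id, , drop = FALSE]
  D
}

write_id_matrix <- function(x, ids, path, fmt = "%d") {
  txt <- apply(x, 1, function(row) paste(sprintf(fmt, row), collapse = " "))
  writeLines(paste(ids, txt), path)
}

#' Write imputation outputs
#'
#' Writes four files under `prefix`: `<prefix>.genotypes.txt` (codes 0/1/2/9),
#' `<prefix>.phase.txt` (two rows per individual, 0/1/9),
#' `<prefix>.dosages.txt` (fixed point, 4 decimals) and
#' `<prefix>.alleleprobs.txt` (two rows per individual, 4 decimals).
#'
#' @param result an `imputation_result` as returned by [run_hybrid()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(result, prefix) {
  ids <- result$pedigree$id
  ids2 <- rep(ids, each = 2)
  paths <- paste0(prefix, c(".genotypes.txt", ".phase.txt",
                            ".dosages.txt", ".alleleprobs.txt"))
  write_id_matrix(result$genotypes, ids, paths[1])
  write_id_matrix(result$phase, ids2, paths[2])
  write_id_matrix(result$dosages, ids, paths[3], fmt = "%.4f")
  write_id_matrix(result$allele_probs, ids2, paths[4], fmt = "%.4f")
  invisible(paths)
}
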