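#' Load a molecule library from a SMILES fixture file
#'
#' The library format is plain text, one record per line:
#' `id<TAB>smiles`. Multi-fragment records (dot-separated SMILES) model
#' clusters of molecules drawn in close proximity, as found in patent
#' figures. Heavy-atom counts and total atom counts (hydrogens included)
#' are computed with OpenBabel and attached to each record.
#'
#' @param path TSV file; default: the packaged fixture library
#' @return data.frame of class `chemseg_library` with columns `id`,
#'   `smiles`, `heavy_atoms`, `total_atoms`, `n_fragments`
#' @export
molecule_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "molecules.tsv", package = "chemseg")
  key <- normalizePath(path)
  if (!is.null(the$library_cache[[key]])) return(the$library_cache[[key]])
  tab <- utils::read.table(path, sep = "\t", quote = "",
                           col.names = c("id", "smiles"),
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab$id)) stop("duplicate molecule ids in library")
  counts <- obabel_atom_counts(tab$smiles, tab$id)
  tab$heavy_atoms <- counts$heavy
  tab$total_atoms <- counts$total
  tab$n_fragments <- lengths(strsplit(tab$smiles, ".", fixed = TRUE))
  class(tab) <- c("chemseg_library", "data.frame")
  if (is.null(the$library_cache)) the$library_cache <- list()
  the$library_cache[[key]] <- tab
  tab
}

check_obabel <- function() {
  if (!nzchar(Sys.which("obabel")))
    stop("OpenBabel ('obabel') is required on the PATH for molecule ",
         "depiction and atom counting")
}

# Batch heavy/total atom counts via two OpenBabel conversions
# (plain SDF for heavy atoms; SDF with explicit hydrogens for totals).
obabel_atom_counts <- function(smiles, ids) {
  check_obabel()
  smi <- tempfile(fileext = ".smi")
  on.exit(unlink(smi))
  writeLines(paste(smiles, ids), smi)
  no_h <- parse_sdf_records(obabel_run(c("-ismi", smi, "-osdf")))
  with_h <- parse_sdf_records(obabel_run(c("-ismi", smi, "-osdf", "-h")))
  if (length(no_h) != length(smiles) || length(with_h) != length(smiles))
    stop("OpenBabel failed to convert ", length(smiles) - length(no_h),
         " library record(s); check SMILES validity")
  list(heavy = vapply(no_h, function(r) sum(r$atoms$symbol != "H"), 0L),
       total = vapply(with_h, function(r) nrow(r$atoms), 0L))
}

obabel_run <- function(args) {
  out <- suppressWarnings(system2("obabel", args, stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) stop("obabel exited with status ", status)
  out
}

# Parse a (possibly multi-record) V2000 SDF into atoms/bonds tables.
parse_sdf_records <- function(lines) {
  if (length(lines) == 0) return(list())
  ends <- which(lines == "$$$$")
  starts <- c(1L, head(ends, -1) + 1L)
  mapply(function(s, e) {
    rec <- lines[s:e]
    na <- as.integer(substr(rec[4], 1, 3))
    nb <- as.integer(substr(rec[4], 4, 6))
    at <- rec[5:(4 + na)]
    atoms <- data.frame(
      x = as.numeric(substr(at, 1, 10)),
      y = as.numeric(substr(at, 11, 20)),
      symbol = trimws(substr(at, 32, 34)),
      stringsAsFactors = FALSE)
    bonds <- if (nb > 0) {
      bl <- rec[(5 + na):(4 + na + nb)]
      data.frame(i = as.integer(substr(bl, 1, 3)),
                 j = as.integer(substr(bl, 4, 6)),
                 order = as.integer(substr(bl, 7, 9)))
    } else data.frame(i = integer(), j = integer(), order = integer())
    list(title = rec[1], atoms = atoms, bonds = bonds)
  }, starts, ends, SIMPLIFY = FALSE)
}

# 2D depiction coordinates for one single-fragment SMILES, cached.
fragment_coords <- function(smiles) {
  if (is.null(the$coord_cache)) the$coord_cache <- new.env(parent = emptyenv())
  hit <- the$coord_cache[[smiles]]
  if (!is.null(hit)) return(hit)
  check_obabel()
  rec <- parse_sdf_records(obabel_run(c(shQuote(paste0("-:", smiles)),
                                        "-osdf", "--gen2d")))
  if (length(rec) != 1L || nrow(rec[[1]]$atoms) == 0)
    stop("depiction failed for SMILES: ", smiles)
  the$coord_cache[[smiles]] <- rec[[1]]
  rec[[1]]
}

#' Select single drug-like molecules for one page
#'
#' Filters the library to single-fragment records whose heavy-atom count
#' lies within `[cfg$min_heavy, cfg$max_heavy]` and samples `n` of them
#' without replacement.
#'
#' @param library a [molecule_library()]
#' @param cfg a [synthesis_config()]
#' @param n number of molecules to draw
#' @return data.frame of `n` selected records
#' @export
select_single_molecules <- function(library, cfg = synthesis_config(), n = 1L) {
  elig <- library[library$n_fragments == 1L &
                  library$heavy_atoms >= cfg$min_heavy &
                  library$heavy_atoms <= cfg$max_heavy, , drop = FALSE]
  if (nrow(elig) == 0L)
    stop("no eligible molecules: none with heavy atoms in [",
         cfg$min_heavy, ", ", cfg$max_heavy, "]")
  if (n > nrow(elig))
    stop("requested ", n, " molecules but only ", nrow(elig), " are eligible")
  elig[sample(nrow(elig), n), , drop = FALSE]
}

#' Select one multi-molecule cluster record
#'
#' Returns a record whose total atom count (hydrogens included) lies
#' within `[cfg$min_cluster_atoms, cfg$max_cluster_atoms]`, drawn
#' uniformly among eligible records.
#'
#' @inheritParams select_single_molecules
#' @return single-row data.frame
#' @export
select_cluster_record <- function(library, cfg = synthesis_config()) {
  elig <- library[library$total_atoms >= cfg$min_cluster_atoms &
                  library$total_atoms <= cfg$max_cluster_atoms, , drop = FALSE]
  if (nrow(elig) == 0L)
    stop("no eligible molecules: none with total atoms in [",
         cfg$min_cluster_atoms, ", ", cfg$max_cluster_atoms, "]")
  elig[sample(nrow(elig), 1L), , drop = FALSE]
}
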