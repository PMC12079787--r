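# Dataset persistence. A dataset directory holds:
#   manifest.json  - counts, units, per-molecule/bond accounting
#   records.json   - full-precision records grouped molecule -> bond -> step
#   frames.extxyz  - flat extended-XYZ export (comment line carries
#                    provenance and label key=value pairs)

#' Build dataset records from a trajectory, optionally labelling them
#'
#' Combines every saved conformer of a `trajectory_result` with its
#' schedule metadata and, when a calculator is given, a
#' [label_geometry()] label (energy, forces, dipole, multi-temperature
#' N_FOD). Labelled geometries whose evaluation fails are dropped and
#' counted as discarded.
#'
#' @param trajectory a `trajectory_result`.
#' @param calc optional `bb_calculator` used for labelling.
#' @param temperatures electronic temperatures for N_FOD labels (K).
#' @return list of dataset records (class `dataset_record`).
#' @export
collect_records <- function(trajectory, calc = NULL,
                            temperatures = c(0, 1000, 5000)) {
  geoms <- c(trajectory$opt_geometries, trajectory$md_geometries)
  steps <- trajectory$steps
  out <- list()
  for (g in geoms) {
    st <- g$provenance$step
    label <- NULL
    if (!is.null(calc)) {
      label <- label_geometry(g, calc, temperatures)
      if (isTRUE(label$discarded)) next
    }
    out[[length(out) + 1L]] <- structure(list(
      geometry = g,
      label = label,
      target_distance = steps$target[steps$step == st],
      stage = steps$stage[steps$step == st],
      converged = steps$converged[steps$step == st]
    ), class = "dataset_record")
  }
  out
}

record_to_list <- function(r) {
  g <- r$geometry
  out <- list(
    elements = g$elements,
    coords = unname(apply(g$coords, 1, as.numeric, simplify = FALSE)),
    provenance = g$provenance,
    target_distance = r$target_distance,
    stage = r$stage,
    converged = r$converged
  )
  if (!is.null(r$label)) {
    out$label <- list(
      energy = r$label$energy,
      forces = unname(apply(r$label$forces, 1, as.numeric, simplify = FALSE)),
      dipole = as.numeric(r$label$dipole),
      n_fod = as.list(r$label$n_fod_by_temperature)
    )
  }
  out
}

record_from_list <- function(x, index) {
  need <- c("elements", "coords", "provenance", "target_distance", "stage",
            "converged")
  missing_f <- setdiff(need, names(x))
  if (length(missing_f) > 0) {
    stop(sprintf("record %d: missing field(s) %s", index,
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  }
  coords <- do.call(rbind, lapply(x$coords, function(p) as.numeric(unlist(p))))
  prov <- x$provenance
  prov$bond <- as.integer(unlist(prov$bond))
  g <- geometry(unlist(x$elements), coords, provenance = prov)
  label <- NULL
  if (!is.null(x$label)) {
    fod <- unlist(x$label$n_fod)
    if (is.null(fod)) fod <- stats::setNames(numeric(0), character(0))
    label <- structure(list(
      energy = x$label$energy,
      forces = do.call(rbind, lapply(x$label$forces,
                                     function(p) as.numeric(unlist(p)))),
      dipole = as.numeric(unlist(x$label$dipole)),
      n_fod_by_temperature = fod,
      discarded = FALSE
    ), class = "conformer_label")
  }
  structure(list(geometry = g, label = label,
                 target_distance = x$target_distance, stage = x$stage,
                 converged = x$converged),
            class = "dataset_record")
}

#' Write a conformer dataset to disk
#'
#' Persists records in a hierarchical JSON container (grouped molecule ->
#' bond -> step, full double precision) together with a flat extended-XYZ
#' export, and writes a manifest with per-origin counts and the declared
#' unit system (eV / Angstrom).
#'
#' @param records list of `dataset_record` (from [collect_records()]).
#' @param path dataset directory (created if needed).
#' @param discarded_count number of discarded geometries to record in the
#'   manifest.
#' @return the manifest, invisibly.
#' @export
write_dataset <- function(records, path, discarded_count = 0L) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create dataset directory: ", path,
                              call. = FALSE)
  origins <- vapply(records, function(r) r$geometry$provenance$origin, "")
  mols <- vapply(records, function(r) r$geometry$provenance$molecule_id, "")
  bonds <- vapply(records, function(r) paste(r$geometry$provenance$bond,
                                             collapse = "-"), "")
  manifest <- list(
    n_total = length(records),
    n_opt = sum(origins == "opt"),
    n_md = sum(origins == "md"),
    n_discarded = as.integer(discarded_count),
    units = list(energy = "eV", length = "angstrom"),
    molecules = lapply(split(seq_along(records), mols)[unique(mols)],
                       function(idx) {
                         list(n = length(idx),
                              bonds = as.list(table(bonds[idx])))
                       })
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # hierarchical container: molecule -> bond -> step -> records
  tree <- list()
  for (i in seq_along(records)) {
    p <- records[[i]]$geometry$provenance
    m <- as.character(p$molecule_id)
    b <- paste(p$bond, collapse = "-")
    s <- sprintf("step%02d", p$step)
    tree[[m]][[b]][[s]] <- c(tree[[m]][[b]][[s]],
                             list(record_to_list(records[[i]])))
  }
  jsonlite::write_json(tree, file.path(path, "records.json"),
                       auto_unbox = TRUE, digits = NA)

  write_extxyz(records, file.path(path, "frames.extxyz"))
  invisible(manifest)
}

#' Read a manifest written by [write_dataset()]
#' @param path dataset directory.
#' @return manifest list.
#' @export
read_manifest <- function(path) {
  f <- file.path(path, "manifest.json")
  if (!file.exists(f)) stop("no manifest.json under ", path, call. = FALSE)
  jsonlite::read_json(f, simplifyVector = FALSE)
}

#' Read a conformer dataset
#'
#' Reads the hierarchical container back into validated `dataset_record`s
#' (round trip is lossless to full double precision). Malformed records
#' are reported with their index; a record-count mismatch against the
#' manifest is an error.
#'
#' @param path dataset directory written by [write_dataset()].
#' @return list of `dataset_record`, with the manifest as attribute
#'   `"manifest"`.
#' @export
read_dataset <- function(path) {
  f <- file.path(path, "records.json")
  if (!file.exists(f)) stop("no records.json under ", path, call. = FALSE)
  tree <- jsonlite::read_json(f, simplifyVector = FALSE)
  records <- list()
  idx <- 0L
  for (m in tree) for (b in m) for (s in b) for (x in s) {
    idx <- idx + 1L
    records[[idx]] <- record_from_list(x, idx)
  }
  manifest <- read_manifest(path)
  if (manifest$n_total != length(records)) {
    stop(sprintf("manifest n_total (%d) does not match records read (%d)",
                 manifest$n_total, length(records)), call. = FALSE)
  }
  attr(records, "manifest") <- manifest
  records
}

fmt_prov_value <- function(v) {
  v <- paste(v, collapse = "-")
  gsub("[[:space:]]", "_", v)
}

#' Write geometries or dataset records as extended XYZ
#'
#' Each frame's comment line declares
#' `Properties=species:S:1:pos:R:3` plus provenance (and, for labelled
#' records, energy and N_FOD) as `key=value` pairs.
#'
#' @param x list of `bb_geometry` or `dataset_record`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_extxyz <- function(x, file) {
  con <- file(file, open = "w")
  on.exit(close(con))
  for (item in x) {
    g <- if (inherits(item, "dataset_record")) item$geometry else item
    p <- g$provenance
    kv <- c("Properties=species:S:1:pos:R:3",
            sprintf("molecule_id=%s", fmt_prov_value(p$molecule_id)),
            sprintf("bond=%s", fmt_prov_value(p$bond)),
            sprintf("step=%s", fmt_prov_value(p$step)),
            sprintf("origin=%s", fmt_prov_value(p$origin)),
            sprintf("snapshot=%s", fmt_prov_value(p$snapshot)))
    if (inherits(item, "dataset_record") && !is.null(item$label)) {
      kv <- c(kv, sprintf("energy=%.10e", item$label$energy))
      fod <- item$label$n_fod_by_temperature
      if (length(fod) > 0) {
        kv <- c(kv, sprintf("n_fod_%sK=%.10e", names(fod), fod))
      }
    }
    writeLines(as.character(length(g$elements)), con)
    writeLines(paste(kv, collapse = " "), con)
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f", g$elements,
                       g$coords[, 1], g$coords[, 2], g$coords[, 3]), con)
  }
  invisible(file)
}

#' Read an extended-XYZ file into geometries
#'
#' Accepts files written by [write_extxyz()] or any conforming extended
#' XYZ. Truncated frames raise an error naming the frame index.
#'
#' @param file path to an extended-XYZ file.
#' @return list of `bb_geometry`; each carries a `comment_fields` attribute
#'   with the parsed key=value pairs.
#' @export
read_extxyz <- function(file) {
  lines <- readLines(file)
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1) {
      stop(sprintf("frame %d: invalid atom count line", frame), call. = FALSE)
    }
    if (i + 1L + nat > length(lines)) {
      stop(sprintf("frame %d: truncated (expected %d atom lines)", frame, nat),
           call. = FALSE)
    }
    comment <- lines[i + 1L]
    toks <- regmatches(comment, gregexpr("[^ =]+=[^ ]+", comment))[[1]]
    fields <- stats::setNames(sub("^[^=]+=", "", toks), sub("=.*$", "", toks))
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(atom_lines), "[[:space:]]+")
    bad <- which(vapply(parts, length, 1L) < 4)
    if (length(bad) > 0) {
      stop(sprintf("frame %d: malformed atom line %d", frame, bad[1]),
           call. = FALSE)
    }
    elements <- vapply(parts, `[[`, "", 1)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    prov <- list()
    if (!is.null(fields["molecule_id"]) && !is.na(fields["molecule_id"])) {
      prov$molecule_id <- unname(fields["molecule_id"])
    }
    has <- function(nm) !is.na(fields[nm]) && fields[[nm]] != "NA"
    for (nm in c("step", "snapshot")) {
      if (has(nm)) prov[[nm]] <- as.integer(fields[[nm]])
    }
    if (has("origin")) prov$origin <- fields[["origin"]]
    if (has("bond")) {
      prov$bond <- as.integer(strsplit(fields[["bond"]], "-")[[1]])
    }
    g <- geometry(elements, coords, provenance = prov)
    attr(g, "comment_fields") <- fields
    out[[frame]] <- g
    i <- i + 2L + nat
  }
  out
}
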