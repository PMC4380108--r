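# Grid pipelines over many samples x many targets, with per-cell isolation:
# one failing gene never aborts the grid. The assembly pipeline emits a
# results table plus per-cell FASTA/trace outputs; the alignment pipeline
# filters best contigs by reciprocal best hit and stacks them on reference
# coordinates into one alignment per target.

#' Construct a pipeline manifest
#'
#' @param samples Tibble with `sample_id` and `db_path` (directories made by
#'   [build_db()]).
#' @param targets Target tibble with `id` and `seq` (DNA or protein;
#'   alphabets may be mixed).
#' @param params An [genefish_params()].
#' @param output_dir Directory for per-cell outputs (created on run).
#' @return A `genefish_manifest`.
#' @export
pipeline_manifest <- function(samples, targets, params = genefish_params(),
                              output_dir = tempfile("genefish_out")) {
  errs <- character()
  if (!is.data.frame(samples) || !all(c("sample_id", "db_path") %in% names(samples)) ||
      nrow(samples) == 0)
    errs <- c(errs, "samples must be a non-empty tibble with sample_id and db_path")
  else {
    if (anyDuplicated(samples$sample_id))
      errs <- c(errs, "sample_ids must be unique")
    missing <- samples$db_path[!vapply(samples$db_path, dir.exists, logical(1))]
    if (length(missing))
      errs <- c(errs, paste0("database path does not exist: ", missing[1]))
  }
  if (!is.data.frame(targets) || !all(c("id", "seq") %in% names(targets)) ||
      nrow(targets) == 0)
    errs <- c(errs, "targets must be a non-empty tibble with id and seq")
  else if (anyDuplicated(targets$id))
    errs <- c(errs, "target ids must be unique")
  if (length(errs)) stop("manifest validation failed:\n  - ",
                         paste(errs, collapse = "\n  - "))
  structure(list(samples = as_tibble(samples), targets = as_tibble(targets),
                 params = params, output_dir = output_dir),
            class = "genefish_manifest")
}

#' Read a plain-text pipeline manifest
#'
#' Format: `key=value` lines for parameters (`output_dir`, `max_iterations`,
#' `fraction`, `autocomplete`), a `[samples]` section of
#' `sample_id<TAB>db_path` lines, and a `[targets]` section of
#' `target_id<TAB>fasta_path` lines (the record with that id, or the only
#' record, is taken from each FASTA).
#'
#' @param path Manifest file path.
#' @param params Baseline [genefish_params()] that file keys override.
#' @return A `genefish_manifest`.
#' @export
read_manifest <- function(path, params = genefish_params()) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  kv <- list()
  samples <- list()
  targets <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) { section <- gsub("[][]", "", ln); next }
    if (section == "") {
      key <- sub("=.*$", "", ln)
      kv[[key]] <- sub("^[^=]*=", "", ln)
    } else if (section == "samples") {
      f <- strsplit(ln, "\t|\\s{2,}| ")[[1]]
      samples[[length(samples) + 1L]] <- tibble(sample_id = f[1], db_path = f[2])
    } else if (section == "targets") {
      f <- strsplit(ln, "\t|\\s{2,}| ")[[1]]
      targets[[length(targets) + 1L]] <- tibble(id = f[1], path = f[2])
    }
  }
  if (!is.null(kv$max_iterations)) params$max_iterations <- as.integer(kv$max_iterations)
  if (!is.null(kv$fraction)) params$fraction <- as.numeric(kv$fraction)
  if (!is.null(kv$autocomplete)) params$autocomplete <- as.logical(kv$autocomplete)
  tg <- bind_rows(targets)
  seqs <- vapply(seq_len(nrow(tg)), function(i) {
    recs <- read_seqs(tg$path[i])
    j <- match(tg$id[i], recs$id)
    if (is.na(j)) j <- 1L
    recs$seq[j]
  }, "")
  pipeline_manifest(bind_rows(samples), tibble(id = tg$id, seq = seqs),
                    params, kv$output_dir %||% tempfile("genefish_out"))
}

#' Run the assembly grid: every target against every sample
#'
#' Calls [run_genefish()] for each (sample, target) cell, writing per-cell
#' `<sample>__<target>.best.fasta`, `.all.fasta` and `.trace.tsv` plus a
#' grid-level `results.tsv`. A failing cell is recorded in its row and never
#' aborts the grid; the results table always has
#' `nrow(samples) * nrow(targets)` rows.
#'
#' @param manifest A `genefish_manifest`.
#' @return A `genefish_grid`: the results tibble with the manifest attached
#'   as attributes, cells in sample-major order.
#' @export
assembly_pipeline <- function(manifest) {
  stopifnot(inherits(manifest, "genefish_manifest"))
  dir.create(manifest$output_dir, recursive = TRUE, showWarnings = FALSE)
  best_contigs <- list()
  rows <- list()
  for (si in seq_len(nrow(manifest$samples))) {
    sid <- manifest$samples$sample_id[si]
    db <- load_db(manifest$samples$db_path[si])
    for (ti in seq_len(nrow(manifest$targets))) {
      tid <- manifest$targets$id[ti]
      cell <- paste0(sid, "__", tid)
      res <- tryCatch(
        run_genefish(db, manifest$targets[ti, ], manifest$params),
        error = function(e) e)
      if (inherits(res, "error")) {
        message("[", cell, "] failed: ", conditionMessage(res))
        rows[[cell]] <- tibble(sample_id = sid, target_id = tid,
                               termination = "error", iterations = NA_integer_,
                               best_contig_id = NA_character_,
                               best_length = NA_integer_, best_score = NA_integer_,
                               error = conditionMessage(res))
        next
      }
      message("[", cell, "] ", res$termination, " after ",
              length(res$trace), " iteration(s)")
      tr <- tidy(res)
      write.table(tr, file.path(manifest$output_dir, paste0(cell, ".trace.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      fc <- res$final_contigs
      if (!is.null(fc) && nrow(fc)) {
        write_fasta(tibble(id = paste0(cell, "_", fc$contig_id), seq = fc$seq),
                    file.path(manifest$output_dir, paste0(cell, ".all.fasta")))
        write_fasta(tibble(id = paste0(cell, "_", res$best_contig$contig_id),
                           seq = res$best_contig$seq),
                    file.path(manifest$output_dir, paste0(cell, ".best.fasta")))
        best_contigs[[cell]] <- res$best_contig
      }
      rows[[cell]] <- tibble(sample_id = sid, target_id = tid,
                             termination = res$termination,
                             iterations = length(res$trace),
                             best_contig_id = res$best_contig$contig_id %||% NA_character_,
                             best_length = res$best_contig$length %||% NA_integer_,
                             best_score = res$best_contig$score %||% NA_integer_,
                             error = NA_character_)
    }
  }
  results <- bind_rows(rows)
  write.table(results, file.path(manifest$output_dir, "results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  structure(results, best_contigs = best_contigs, manifest = manifest,
            class = c("genefish_grid", class(results)))
}

# stack sample contigs on the coordinates of their reference target:
# each contig is pairwise-aligned to the reference; per reference position
# the contig base (or '-') is taken, and interior insertions relative to the
# reference (introns) are padded to the per-junction maximum across samples.
# contig overhangs beyond the reference ends are not part of the gene and
# are trimmed.
stack_on_reference <- function(ref_seq, contigs, scheme = metric_scheme()) {
  n_ref <- nchar(ref_seq)
  per_pos <- list()   # sample -> character vector of length n_ref
  inserts <- list()   # sample -> list: junction index (0..n_ref) -> string
  for (sid in names(contigs)) {
    fwd <- semi_global_align(ref_seq, contigs[[sid]], scheme)
    rev <- semi_global_align(ref_seq, as.character(cpp_revcomp(contigs[[sid]])), scheme)
    al <- if (rev$score > fwd$score) rev else fwd
    ra <- strsplit(al$a, "", fixed = TRUE)[[1]]
    rb <- strsplit(al$b, "", fixed = TRUE)[[1]]
    pos <- 0L
    bases <- rep("-", n_ref)
    ins <- list()
    buf <- ""
    for (k in seq_along(ra)) {
      if (ra[k] == "-") {
        buf <- paste0(buf, rb[k])
      } else {
        # store an insertion only at interior junctions; leading buffer
        # content (pos == 0) is contig overhang, not gene sequence
        if (nzchar(buf)) { if (pos > 0L) ins[[as.character(pos)]] <- buf; buf <- "" }
        pos <- pos + 1L
        bases[pos] <- rb[k]
      }
    }
    per_pos[[sid]] <- bases
    inserts[[sid]] <- ins
  }
  junctions <- sort(unique(as.integer(unlist(lapply(inserts, names)))))
  ins_width <- setNames(integer(length(junctions)), as.character(junctions))
  for (j in as.character(junctions))
    ins_width[j] <- max(vapply(inserts, function(x) nchar(x[[j]] %||% ""), 1L))
  out <- vapply(names(per_pos), function(sid) {
    pieces <- character()
    for (p in 0:n_ref) {
      jp <- as.character(p)
      if (jp %in% names(ins_width)) {
        s <- inserts[[sid]][[jp]] %||% ""
        pieces <- c(pieces, formatC(s, width = -ins_width[jp], flag = "-"))
      }
      if (p < n_ref) pieces <- c(pieces, per_pos[[sid]][p + 1L])
    }
    gsub(" ", "-", paste(pieces, collapse = ""))
  }, "")
  out
}

#' Run the alignment pipeline: per-target multiple alignments
#'
#' Assembles every (sample, target) cell (or reuses a [assembly_pipeline()]
#' result), keeps each sample's best contig that passes the reciprocal
#' best-hit test against the reference protein set, and stacks the passing
#' contigs on reference coordinates into one gapped FASTA per target.
#' Targets with fewer than two passing samples are skipped with a message.
#'
#' @param manifest A `genefish_manifest`. DNA targets are translated (frame
#'   0) to form the reference proteome; protein targets are used directly.
#' @param grid Optional precomputed [assembly_pipeline()] result for this
#'   manifest.
#' @return Named list (by target id) of named character vectors of aligned
#'   rows; skipped targets are absent. Written as
#'   `<output_dir>/<target>.aln.fasta`.
#' @export
alignment_pipeline <- function(manifest, grid = NULL) {
  stopifnot(inherits(manifest, "genefish_manifest"))
  if (is.null(grid)) grid <- assembly_pipeline(manifest)
  best <- attr(grid, "best_contigs")
  alphabet <- guess_alphabet(manifest$targets$seq)
  proteome <- tibble(
    id = manifest$targets$id,
    seq = ifelse(alphabet == "protein", toupper(manifest$targets$seq),
                 vapply(manifest$targets$seq,
                        function(s) sub("\\*$", "", translate_six_frames(s)[1]),
                        "", USE.NAMES = FALSE)))
  alignments <- list()
  for (ti in seq_len(nrow(manifest$targets))) {
    tid <- manifest$targets$id[ti]
    passing <- list()
    for (sid in manifest$samples$sample_id) {
      bc <- best[[paste0(sid, "__", tid)]]
      if (is.null(bc)) next
      call <- reciprocal_best_hit(bc, tid, proteome)
      if (isTRUE(call$is_ortholog)) passing[[sid]] <- bc$seq
    }
    if (length(passing) < 2L) {
      message("[", tid, "] skipped: ", length(passing), " passing sample(s)")
      next
    }
    if (alphabet[ti] != "dna") {
      message("[", tid, "] skipped: reference-anchored stacking needs a DNA target")
      next
    }
    ref <- normalize_dna(manifest$targets$seq[ti])
    rows <- stack_on_reference(ref, passing)
    alignments[[tid]] <- rows
    write_fasta(tibble(id = names(rows), seq = unname(rows)),
                file.path(manifest$output_dir, paste0(tid, ".aln.fasta")))
  }
  alignments
}
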