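#' Write / read a cohort as plain-text files
#'
#' Directory layout: `subjects.tsv` (id, group, sex, behavior and covariate
#' columns), one `fc_<id>.tsv` per subject (dense node-by-node matrix,
#' tab-separated, no headers) or `ts_<id>.tsv` (node-by-time), and
#' `atlas.tsv` (node_index, name, hemisphere, lobe, gyrus, network).
#' Node indexing is 0-based in all files. `spec.yaml` mirrors the
#' generating [cohort_spec()] field-for-field when present.
#'
#' `read_cohort(write_cohort(co))` reproduces the cohort up to
#' floating-point text representation (15 significant digits).
#'
#' @param cohort a `cpm_cohort`.
#' @param dir directory to create/populate, or to read.
#' @return `write_cohort`: invisibly, `dir`. `read_cohort`: a `cpm_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE)
  wt <- function(x, path, col.names) {
    if (is.data.frame(x)) {
      x[] <- lapply(x, function(col) if (is.numeric(col)) fmt(col) else col)
    } else {
      x <- fmt(x)
    }
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
  }
  wt(cohort$subjects, file.path(dir, "subjects.tsv"), col.names = TRUE)
  wt(cohort$atlas, file.path(dir, "atlas.tsv"), col.names = TRUE)
  for (sid in cohort$subjects$id) {
    if (!is.null(cohort$ts) && !is.null(cohort$ts[[sid]]))
      wt(cohort$ts[[sid]], file.path(dir, sprintf("ts_%s.tsv", sid)),
         col.names = FALSE)
    else
      wt(cohort$fc[[sid]], file.path(dir, sprintf("fc_%s.tsv", sid)),
         col.names = FALSE)
  }
  if (!is.null(cohort$spec)) write_cohort_spec(cohort$spec, file.path(dir, "spec.yaml"))
  invisible(dir)
}

write_cohort_spec <- function(spec, path) {
  s <- unclass(spec)
  s$behavior <- mat_to_yaml(s$behavior)
  s$covariates <- mat_to_yaml(s$covariates)
  s$planted_positive_edges <- apply(s$planted_positive_edges, 1, as.integer,
                                    simplify = FALSE)
  s$group_sizes <- as.list(s$group_sizes)
  s$sex_male_counts <- as.list(s$sex_male_counts)
  yaml::write_yaml(s, path)
}

mat_to_yaml <- function(m) {
  out <- lapply(seq_len(nrow(m)), function(r) as.list(m[r, ]))
  names(out) <- rownames(m)
  out
}

yaml_to_mat <- function(lst) {
  m <- do.call(rbind, lapply(lst, function(r) unlist(r)))
  rownames(m) <- names(lst)
  m
}

read_cohort_spec <- function(path) {
  s <- yaml::read_yaml(path)
  cohort_spec(
    n_nodes = s$n_nodes,
    group_sizes = unlist(s$group_sizes),
    behavior = yaml_to_mat(s$behavior),
    covariates = yaml_to_mat(s$covariates),
    sex_male_counts = unlist(s$sex_male_counts),
    planted_positive_edges = do.call(rbind, lapply(s$planted_positive_edges,
                                                   as.integer)),
    behavior_target = s$behavior_target,
    edge_behavior_r = s$edge_behavior_r,
    subtype_diff_edge = s$subtype_diff_edge,
    subtype_diff_d = s$subtype_diff_d,
    fc_mean = s$fc_mean,
    fc_between_sd = s$fc_between_sd,
    noise_sd = s$noise_sd,
    n_timepoints = s$n_timepoints,
    seed = s$seed
  )
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  spath <- file.path(dir, "subjects.tsv")
  if (!file.exists(spath)) stop("missing subjects.tsv in ", dir)
  subjects <- utils::read.table(spath, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE,
                                colClasses = c(id = "character"))
  need <- c("id", "group", "sex", "age", "education", "illness_duration", "fd")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop("subjects.tsv is missing column(s): ", paste(miss, collapse = ", "))
  atlas <- utils::read.table(file.path(dir, "atlas.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  assert_atlas(atlas)
  n <- nrow(atlas)

  fc <- list(); ts <- list()
  for (sid in subjects$id) {
    fpath <- file.path(dir, sprintf("fc_%s.tsv", sid))
    tpath <- file.path(dir, sprintf("ts_%s.tsv", sid))
    if (file.exists(fpath)) {
      m <- as.matrix(utils::read.table(fpath, sep = "\t", header = FALSE))
      dimnames(m) <- NULL
      if (nrow(m) != n || ncol(m) != n)
        stop(sprintf("%s: %dx%d matrix does not match %d atlas nodes",
                     basename(fpath), nrow(m), ncol(m), n))
      if (max(abs(m - t(m))) > 1e-8)
        stop(basename(fpath), ": FC matrix is not symmetric")
      diag(m) <- 1
      assert_fc(m, tol = 1e-8)
      fc[[sid]] <- m
    } else if (file.exists(tpath)) {
      m <- as.matrix(utils::read.table(tpath, sep = "\t", header = FALSE))
      dimnames(m) <- NULL
      if (nrow(m) != n)
        stop(sprintf("%s: %d rows do not match %d atlas nodes",
                     basename(tpath), nrow(m), n))
      ts[[sid]] <- m
    } else {
      stop("subject ", sid, ": neither fc_ nor ts_ file found in ", dir)
    }
  }
  spec <- NULL
  ypath <- file.path(dir, "spec.yaml")
  if (file.exists(ypath)) spec <- read_cohort_spec(ypath)
  structure(
    list(subjects = subjects,
         fc = if (length(fc)) fc else NULL,
         ts = if (length(ts)) ts else NULL,
         atlas = atlas, n_nodes = n, spec = spec),
    class = "cpm_cohort")
}
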