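#' Per-core feature matrix
#'
#' Rows are cores of a single compartment variant; the numeric matrix is
#' accompanied by aligned `patient_id` / `core_id` vectors. The container
#' enforces the study inclusion rule that every patient contributes at
#' least two cores and that core identifiers are unique.
#'
#' @param features Numeric matrix, one row per core.
#' @param patient_id,core_id Character vectors aligned with the rows.
#' @param variant Compartment variant of all rows.
#' @param check_min_cores Enforce the >= 2 cores per patient invariant
#'   (disable only for intermediate objects).
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(features, patient_id, core_id,
                           variant = c("original", "epithelium", "stroma"),
                           check_min_cores = TRUE) {
  variant <- match.arg(variant)
  features <- as.matrix(features)
  if (nrow(features) != length(patient_id) ||
      nrow(features) != length(core_id)) {
    stop("patient_id / core_id must align with feature rows")
  }
  if (anyDuplicated(core_id)) stop("duplicated core_id in feature matrix")
  if (nrow(features) > 0 && !all(is.finite(features))) {
    stop("feature matrix contains non-finite entries")
  }
  if (check_min_cores && nrow(features) > 0) {
    bad <- names(which(table(patient_id) < 2))
    if (length(bad)) {
      stop("patients with fewer than 2 cores: ", paste(bad, collapse = ", "))
    }
  }
  rownames(features) <- core_id
  structure(list(features = features,
                 patient_id = as.character(patient_id),
                 core_id = as.character(core_id),
                 variant = variant),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix %d cores x %d features, %d patients, variant=%s>\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$patient_id)), x$variant))
  invisible(x)
}

# package-local cache for the fixed projection matrix
.visith_env <- new.env(parent = emptyenv())

# Fixed seeded Gaussian random projection (n_out x n_in); the global RNG
# state is saved and restored so featurization never perturbs user seeds.
builtin_projection <- function(n_in, n_out) {
  key <- sprintf("proj_%d_%d", n_in, n_out)
  if (!is.null(.visith_env[[key]])) return(.visith_env[[key]])
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(990151L)
  P <- matrix(stats::rnorm(n_in * n_out), n_out, n_in) / sqrt(n_in)
  .visith_env[[key]] <- P
  P
}

# raw colour/texture descriptor of one patch (fixed length)
patch_descriptor <- function(patch) {
  px <- patch$pixels
  q3 <- function(x) stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
  chans <- lapply(1:3, function(b) as.vector(px[, , b]))
  per_chan <- unlist(lapply(chans, function(x) c(mean(x), stats::sd(x), q3(x))))
  gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  n <- nrow(gray); m <- ncol(gray)
  gx <- gray[, -1, drop = FALSE] - gray[, -m, drop = FALSE]
  gy <- gray[-1, , drop = FALSE] - gray[-n, , drop = FALSE]
  grad <- sqrt(gx[-n, , drop = FALSE]^2 + gy[, -m, drop = FALSE]^2)
  core <- gray[2:(n - 1), 2:(m - 1)]
  lap <- 4 * core - gray[1:(n - 2), 2:(m - 1)] - gray[3:n, 2:(m - 1)] -
    gray[2:(n - 1), 1:(m - 2)] - gray[2:(n - 1), 3:m]
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  hist_g <- tabulate(pmin(floor(gray * 16) + 1, 16), 16) / length(gray)
  C <- stain_concentrations(optical_density(px), he_stain_matrix())
  he_stats <- c(mean(C[, 1]), stats::sd(C[, 1]), stats::quantile(C[, 1], 0.9, names = FALSE),
                mean(C[, 2]), stats::sd(C[, 2]), stats::quantile(C[, 2], 0.9, names = FALSE))
  c(per_chan,                              # 15
    mean(gray), stats::sd(gray),           # 2
    mean(grad), stats::sd(grad), stats::quantile(grad, 0.9, names = FALSE),  # 3
    stats::var(as.vector(lap)),            # 1
    mean(sat), stats::sd(sat),             # 2
    hist_g,                                # 16
    he_stats)                              # 6  -> 45 total
}

#' Featurize one image patch
#'
#' The built-in backend computes a deterministic colour/texture descriptor
#' (channel statistics, gradient and Laplacian focus measures, saturation,
#' grey histogram, hematoxylin/eosin concentration statistics) and expands
#' it to `dim` dimensions with a fixed seeded Gaussian projection, so the
#' full pipeline runs offline and bit-reproducibly. A pretrained
#' convolutional backend (VGG16 family, final convolutional block globally
#' pooled to 512) is a documented optional extra and is not bundled.
#'
#' @param patch A `core_patch` that passed filtering.
#' @param backend `"builtin"` (default) or `"vgg16"`.
#' @param dim Output dimension (default 512).
#' @return Numeric vector of length `dim`.
#' @export
extract_patch_features <- function(patch, backend = c("builtin", "vgg16"),
                                   dim = 512) {
  backend <- match.arg(backend)
  if (backend == "vgg16") {
    stop("the pretrained 'vgg16' backend is not bundled with this package; ",
         "use backend = 'builtin' (deterministic descriptor) instead")
  }
  s <- patch_descriptor(patch)
  as.vector(builtin_projection(length(s), dim) %*% s)
}

#' Average patch vectors into one core feature
#'
#' The core descriptor is the element-wise arithmetic mean of its kept
#' patch vectors (permutation-invariant in patch order).
#'
#' @param patch_vectors List (or matrix rows) of equal-length numeric
#'   vectors; at least one.
#' @param patient_id,core_id,variant Metadata for the core.
#' @return List of class `core_feature` with fields `patient_id`,
#'   `core_id`, `variant`, `vector`.
#' @export
aggregate_core <- function(patch_vectors, patient_id, core_id,
                           variant = "original") {
  if (is.matrix(patch_vectors)) {
    patch_vectors <- lapply(seq_len(nrow(patch_vectors)),
                            function(i) patch_vectors[i, ])
  }
  if (length(patch_vectors) == 0) {
    stop("core ", core_id, " has zero kept patches; core must be excluded")
  }
  lens <- vapply(patch_vectors, length, integer(1))
  if (length(unique(lens)) != 1) stop("patch vectors differ in length")
  v <- rowMeans(do.call(cbind, patch_vectors))
  structure(list(patient_id = patient_id, core_id = core_id,
                 variant = variant, vector = v),
            class = "core_feature")
}

#' Assemble core features into a feature matrix
#'
#' Rows are sorted by `patient_id` then `core_id` (the documented stable
#' order). Patients left with fewer than two cores are dropped with a
#' warning, mirroring the study inclusion rule.
#'
#' @param cores List of `core_feature` objects of a single variant.
#' @return A [feature_matrix()] (possibly with zero rows).
#' @export
build_feature_matrix <- function(cores) {
  if (length(cores) == 0) {
    return(feature_matrix(matrix(numeric(0), 0, 0), character(0), character(0)))
  }
  variant <- unique(vapply(cores, `[[`, character(1), "variant"))
  if (length(variant) != 1) stop("cores mix compartment variants")
  pid <- vapply(cores, `[[`, character(1), "patient_id")
  cid <- vapply(cores, `[[`, character(1), "core_id")
  if (anyDuplicated(cid)) {
    stop("duplicate core_id: ", paste(unique(cid[duplicated(cid)]), collapse = ", "))
  }
  ord <- order(pid, cid)
  pid <- pid[ord]; cid <- cid[ord]; cores <- cores[ord]
  keep <- pid %in% names(which(table(pid) >= 2))
  if (!all(keep)) {
    warning("dropping patient(s) with fewer than 2 cores after filtering: ",
            paste(unique(pid[!keep]), collapse = ", "))
  }
  cores <- cores[keep]
  if (length(cores) == 0) {
    return(feature_matrix(matrix(numeric(0), 0, 0), character(0), character(0),
                          variant = variant))
  }
  mat <- do.call(rbind, lapply(cores, `[[`, "vector"))
  feature_matrix(mat, pid[keep], cid[keep], variant = variant)
}

#' Read / write feature matrices as delimited text
#'
#' Tab-separated with header `patient_id, core_id, variant, f_1 ... f_d`.
#' The reader validates dimensions and the >= 2 cores-per-patient rule.
#'
#' @param fm A [feature_matrix()].
#' @param path File path.
#' @return `read_feature_matrix` returns a [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(patient_id = fm$patient_id, core_id = fm$core_id,
                   variant = fm$variant, fm$features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("patient_id", "core_id", "variant",
                    sprintf("f_%d", seq_len(ncol(fm$features))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("patient_id", "core_id", "variant")
  if (!all(need %in% names(df))) stop("malformed feature table: missing id columns")
  fcols <- grep("^f_\\d+$", names(df), value = TRUE)
  if (length(fcols) == 0) stop("malformed feature table: no feature columns")
  variant <- unique(df$variant)
  if (length(variant) != 1) stop("feature table mixes variants")
  feature_matrix(as.matrix(df[fcols]), df$patient_id, df$core_id,
                 variant = variant)
}
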