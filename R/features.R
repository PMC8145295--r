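## Class balancing by deterministic flip/transpose augmentation, deep
## feature extraction behind a pluggable backbone interface, and stratified
## train/test splitting. The desk-scale backbone is the package's own small
## CNN (global-average-pooled conv3, 128 features); pretrained
## ResNet101/DenseNet201 backbones are interface slots that require their
## optional deep-learning dependency.

## the six deterministic augmentation variants, in fixed order
aug_variants <- list(
  identity = function(x) x,
  hflip = function(x) if (is.matrix(x)) x[, rev(seq_len(ncol(x)))] else
    x[, rev(seq_len(ncol(x))), , drop = FALSE],
  vflip = function(x) if (is.matrix(x)) x[rev(seq_len(nrow(x))), ] else
    x[rev(seq_len(nrow(x))), , , drop = FALSE],
  transpose = function(x) if (is.matrix(x)) t(x) else aperm(x, c(2, 1, 3)),
  transpose_hflip = function(x) aug_variants$transpose(aug_variants$hflip(x)),
  transpose_vflip = function(x) aug_variants$transpose(aug_variants$vflip(x))
)

#' Balance classes by deterministic flip/transpose augmentation
#'
#' Each class is grown to exactly `target_per_class` images by cycling, in
#' order, through the six variants \{identity, horizontal flip, vertical
#' flip, transpose, transpose of h-flip, transpose of v-flip\} applied to
#' the originals in their input order. At most six variants exist per
#' original, so `target_per_class <= 6 * class count` must hold.
#'
#' @param images list of images (square for the transposed variants to be
#'   shape-compatible).
#' @param labels factor/character per-image class labels.
#' @param target_per_class target image count for every class; must be at
#'   least the largest class count unless `allow_downsample = TRUE`.
#' @param allow_downsample permit truncating classes larger than the
#'   target.
#' @return list with balanced `images` and `labels`.
#' @export
augment_to_balance <- function(images, labels, target_per_class,
                               allow_downsample = FALSE) {
  labels <- factor(labels)
  if (!allow_downsample && target_per_class < max(table(labels)))
    stop("target_per_class is below the largest class count; ",
         "set allow_downsample = TRUE to truncate")
  out_img <- list(); out_lab <- character(0)
  for (cls in levels(labels)) {
    idx <- which(labels == cls)
    n <- length(idx)
    if (target_per_class > 6L * n)
      stop("class ", cls, ": target ", target_per_class,
           " unreachable with 6 variants of ", n,
           " originals (max ", 6L * n, ")")
    picks <- expand.grid(orig = seq_len(n), variant = seq_along(aug_variants))
    picks <- picks[order(picks$variant, picks$orig), ][seq_len(target_per_class), ]
    for (r in seq_len(nrow(picks))) {
      f <- aug_variants[[picks$variant[r]]]
      out_img[[length(out_img) + 1L]] <- f(images[[idx[picks$orig[r]]]])
      out_lab <- c(out_lab, cls)
    }
  }
  list(images = out_img, labels = factor(out_lab, levels = levels(labels)))
}

#' Backbone specification for deep feature extraction
#'
#' All backbones tap a global-average-pool layer. `tiny-cnn` wraps a
#' trained [saliency_net][build_saliency_net()] and emits its 128-channel
#' conv3 embedding; the pretrained `resnet101`/`densenet201` slots require
#' an R deep-learning runtime and raise an actionable error when it is not
#' installed. The reported `output_dim` is whatever the backbone emits —
#' never hard-coded.
#'
#' @param name one of `"tiny-cnn"`, `"resnet101"`, `"densenet201"`.
#' @param net for `tiny-cnn`: a trained `saliency_net`.
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = c("tiny-cnn", "resnet101", "densenet201"),
                          net = NULL) {
  name <- match.arg(name)
  if (name == "tiny-cnn") {
    if (is.null(net) || !inherits(net, "saliency_net") || !net$trained)
      stop("tiny-cnn backbone needs a trained saliency_net in `net`")
    dim_out <- 128L
  } else {
    dim_out <- NA_integer_
  }
  structure(list(name = name, net = net, pooling = "global-average",
                 output_dim = dim_out), class = "backbone_spec")
}

#' Extract per-image deep features through a backbone
#'
#' @param backbone a [backbone_spec()].
#' @param images list of images in \[0, 255\].
#' @return N x d feature matrix (d = backbone output width; 128 for
#'   tiny-cnn), columns `feat1..featd`.
#' @export
extract_features <- function(backbone, images) {
  stopifnot(inherits(backbone, "backbone_spec"))
  if (backbone$name != "tiny-cnn")
    stop("backbone '", backbone$name, "' requires the optional pretrained ",
         "deep-learning dependency (torch), which is not installed; ",
         "use the tiny-cnn backbone or install the dependency")
  rows <- lapply(images, function(im) tiny_cnn_embedding(backbone$net, im))
  x <- do.call(rbind, rows)
  colnames(x) <- sprintf("feat%d", seq_len(ncol(x)))
  x
}

#' Stratified train/test split of a labeled feature matrix
#'
#' Every class with at least two samples appears in both partitions;
#' singleton classes go to the training partition with a warning.
#'
#' @param x N x d feature matrix.
#' @param labels per-row labels.
#' @param train_frac training fraction in (0, 1).
#' @param seed split seed.
#' @return list with `train` and `test`, each a list of `x`, `labels` and
#'   the original row indices `idx`.
#' @export
split_dataset <- function(x, labels, train_frac = 0.7, seed = 1) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)")
  labels <- factor(labels)
  tr_idx <- integer(0)
  with_seed(seed, {
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      n <- length(idx)
      if (n == 1L) {
        warning("class ", cls, " has a single sample; assigned to train")
        tr_idx <- c(tr_idx, idx)
        next
      }
      n_tr <- min(max(round(train_frac * n), 1L), n - 1L)
      tr_idx <- c(tr_idx, sample(idx, n_tr))
    }
  })
  tr_idx <- sort(tr_idx)
  te_idx <- setdiff(seq_len(nrow(x)), tr_idx)
  list(train = list(x = x[tr_idx, , drop = FALSE],
                    labels = droplevels(labels[tr_idx]), idx = tr_idx),
       test = list(x = x[te_idx, , drop = FALSE],
                   labels = droplevels(labels[te_idx]), idx = te_idx))
}

#' Write a feature matrix with labels as delimited text
#'
#' Comma-delimited with a header row and a final `label` column — the
#' format consumed by the selection, fusion and classification stages.
#' @param x N x d feature matrix.
#' @param labels per-row labels.
#' @param path output file.
#' @export
write_features_csv <- function(x, labels, path) {
  df <- as.data.frame(x)
  df$label <- as.character(labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features_csv()]
#' @param path CSV file with a final `label` column.
#' @return list with `features` (matrix) and `labels` (factor).
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("no 'label' column in ", path)
  labels <- factor(df$label)
  df$label <- NULL
  list(features = as.matrix(df), labels = labels)
}
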