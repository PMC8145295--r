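## End-to-end experiment drivers: the segmentation experiment (enhance ->
## train saliency net -> segment -> evaluate, with an optional ablation of
## the enhancement stage) and the classification experiment (two feature
## streams -> IMFO selection per stream -> correlation fusion -> KELM).

#' Generate a desk-scale segmentation fixture set
#'
#' Two lesion classes at a common contrast, discriminable by lesion color
#' and size: odd seeds draw brown lesions, even seeds red, with randomized
#' ellipse geometry.
#'
#' @param n number of images.
#' @param image_size square side in pixels.
#' @param contrast lesion contrast for every image.
#' @param seed base seed; image i derives its spec from `seed + i`.
#' @return list with `images`, `masks`, `labels` (factor of two classes).
#' @export
generate_segmentation_fixtures <- function(n = 200, image_size = 64,
                                           contrast = 0.4, seed = 1) {
  images <- vector("list", n); masks <- vector("list", n)
  labels <- character(n)
  for (i in seq_len(n)) {
    cls <- 1L + (i %% 2L)
    sp <- random_lesion_spec(image_size, seed = seed * 100000L + i,
                             class_id = cls, contrast = contrast)
    im <- generate_lesion_image(sp)
    images[[i]] <- im$image
    masks[[i]] <- im$mask
    labels[i] <- sprintf("class%d", cls)
  }
  list(images = images, masks = masks, labels = factor(labels))
}

#' Run the deep-saliency segmentation experiment
#'
#' Optionally enhances every image, splits the set 50/50 (stratified by
#' class), trains the saliency network on the training half with the
#' image-level class labels, segments the test half, and evaluates each
#' predicted mask against ground truth. `enhance = FALSE` reproduces the
#' contrast-enhancement ablation arm.
#'
#' @param images,masks,labels lists/vector of images, ground-truth 0/1
#'   masks and class labels; generated via
#'   [generate_segmentation_fixtures()] when `images` is `NULL`.
#' @param n_images,image_size,contrast fixture parameters (used only when
#'   generating).
#' @param train_frac training fraction of the 50/50 protocol.
#' @param enhance apply the contrast-enhancement stage.
#' @param n_segments SLIC superpixel count; `NULL` (default) uses the
#'   scale-consistent count from [scale_n_segments()].
#' @param epochs training epochs for the saliency network. The default is
#'   a single epoch: longer training specializes the third-convolution
#'   channels to the classification task, which measurably *weakens* the
#'   fused saliency map (see the methods vignette).
#' @param seed global experiment seed.
#' @return list of class `segmentation_experiment`: `mean_accuracy`,
#'   `mean_error`, `mean_dice`, `per_image` (data.frame over the test
#'   half), the trained `net`, and `config`.
#' @export
run_segmentation_experiment <- function(images = NULL, masks = NULL,
                                        labels = NULL, n_images = 200,
                                        image_size = 64, contrast = 0.4,
                                        train_frac = 0.5, enhance = TRUE,
                                        n_segments = NULL, epochs = 1,
                                        seed = 1) {
  if (is.null(images)) {
    fx <- generate_segmentation_fixtures(n_images, image_size, contrast,
                                         seed = seed)
    images <- fx$images; masks <- fx$masks; labels <- fx$labels
  }
  if (length(images) == 0) stop("no images to process")
  labels <- factor(labels)
  proc <- if (enhance) lapply(images, lesionkit::enhance) else images
  sp <- split_dataset(matrix(0, length(proc), 1), labels,
                      train_frac = train_frac, seed = seed)
  tr <- sp$train$idx; te <- sp$test$idx
  spec <- saliency_net_spec(input_size = dim(proc[[1]])[1],
                            n_classes = nlevels(labels), epochs = epochs,
                            seed = seed)
  net <- build_saliency_net(spec)
  net <- train_saliency_net(net, proc[tr], labels[tr])
  rows <- lapply(te, function(i) {
    pred <- segment_image(net, proc[[i]], n_segments = n_segments)
    rep_ <- evaluate_segmentation(pred, masks[[i]])
    data.frame(index = i, accuracy = rep_$accuracy, error = rep_$error,
               dice = rep_$dice)
  })
  per_image <- do.call(rbind, rows)
  structure(list(mean_accuracy = mean(per_image$accuracy),
                 mean_error = mean(per_image$error),
                 mean_dice = mean(per_image$dice),
                 per_image = per_image, net = net,
                 config = list(enhance = enhance, train_frac = train_frac,
                               n_segments = n_segments, epochs = epochs,
                               seed = seed)),
            class = "segmentation_experiment")
}

#' @export
print.segmentation_experiment <- function(x, ...) {
  cat(sprintf("Segmentation experiment (%s enhancement, %d test images):\n",
              if (x$config$enhance) "with" else "without",
              nrow(x$per_image)))
  cat(sprintf("  mean accuracy %.2f%% | mean error %.2f%% | mean Dice %.4f\n",
              x$mean_accuracy, x$mean_error, x$mean_dice))
  invisible(x)
}

#' Generate two correlated synthetic feature streams over shared labels
#'
#' Emulates two deep backbones looking at the same images: both streams'
#' informative columns derive from the same class structure (so paired
#' informative columns correlate), while noise columns are independent.
#'
#' @param spec a [feature_dataset_spec()] describing one stream.
#' @param seed base seed (stream 2 uses `seed + 1`).
#' @return list with `stream1`, `stream2` (matrices), `labels`,
#'   `informative_indices`.
#' @export
generate_feature_streams <- function(spec, seed = 1) {
  s1 <- generate_feature_dataset(`class<-`(modifyList(unclass(spec),
                                                      list(seed = seed)),
                                           "feature_dataset_spec"))
  s2 <- generate_feature_dataset(`class<-`(modifyList(unclass(spec),
                                                      list(seed = seed + 1L)),
                                           "feature_dataset_spec"))
  list(stream1 = s1$features, stream2 = s2$features, labels = s1$labels,
       informative_indices = s1$informative_indices)
}

#' Run the multiclass classification experiment
#'
#' Two feature streams are selected independently by the moth-flame
#' wrapper, fused by maximal correlation, and classified with KELM on a
#' stratified 70/30 split. When fusion retains no pair, the selected
#' streams are concatenated instead (recorded in the manifest).
#'
#' @param stream1,stream2 feature matrices (generated from `spec` when
#'   `NULL`).
#' @param labels per-row class labels.
#' @param spec a [feature_dataset_spec()] used when streams are generated.
#' @param variant `"imfo"` or `"mfo"`.
#' @param n_iter,n_pop selection loop parameters (desk-scale default 30
#'   iterations, population 20).
#' @param r_weight fitness trade-off r.
#' @param threshold fusion correlation threshold.
#' @param kernel,C KELM parameters.
#' @param train_frac training fraction.
#' @param seed global seed.
#' @return list of class `classification_experiment` with the
#'   [evaluate_classification()] `report`, per-stream selections, fusion
#'   result and a `manifest` of stage dimensions.
#' @export
run_classification_experiment <- function(stream1 = NULL, stream2 = NULL,
                                          labels = NULL,
                                          spec = feature_dataset_spec(),
                                          variant = c("imfo", "mfo"),
                                          n_iter = 30, n_pop = 20,
                                          r_weight = 0.9, threshold = 0.5,
                                          kernel = "rbf", C = 100,
                                          train_frac = 0.7, seed = 1) {
  variant <- match.arg(variant)
  if (is.null(stream1)) {
    st <- generate_feature_streams(spec, seed = seed)
    stream1 <- st$stream1; stream2 <- st$stream2; labels <- st$labels
  }
  labels <- factor(labels)
  sp <- split_dataset(stream1, labels, train_frac = train_frac, seed = seed)
  tr <- sp$train$idx; te <- sp$test$idx
  cfg <- fitness_config(r_weight = r_weight, seed = seed)
  sel1 <- select_features(stream1[tr, , drop = FALSE], labels[tr], cfg,
                          n_iter = n_iter, n_pop = n_pop, seed = seed,
                          variant = variant)
  sel2 <- select_features(stream2[tr, , drop = FALSE], labels[tr], cfg,
                          n_iter = n_iter, n_pop = n_pop, seed = seed + 1L,
                          variant = variant)
  v1 <- stream1[, sel1$selected_indices, drop = FALSE]
  v2 <- stream2[, sel2$selected_indices, drop = FALSE]
  fus <- fuse_features(v1[tr, , drop = FALSE], v2[tr, , drop = FALSE],
                       fusion_config(correlation_threshold = threshold))
  fused_empty <- fus$k3 == 0
  if (!fused_empty) {
    keep <- fus$source_pairs
    build <- function(rows) {
      p <- pad_to_max_length(v1[rows, , drop = FALSE],
                             v2[rows, , drop = FALSE])
      cols <- lapply(seq_len(nrow(keep)), function(k)
        cbind(p$v1[, keep$i[k]], p$v2[, keep$i[k]]))
      do.call(cbind, cols)
    }
    xtr <- build(tr); xte <- build(te)
  } else {
    xtr <- cbind(v1[tr, , drop = FALSE], v2[tr, , drop = FALSE])
    xte <- cbind(v1[te, , drop = FALSE], v2[te, , drop = FALSE])
  }
  model <- kelm(xtr, labels[tr], kernel = kernel, C = C)
  pred <- predict(model, xte)
  report <- evaluate_classification(pred, labels[te])
  structure(list(report = report, selection1 = sel1, selection2 = sel2,
                 fusion = fus, model = model,
                 manifest = list(variant = variant,
                                 dim_in = c(ncol(stream1), ncol(stream2)),
                                 dim_selected = c(length(sel1$selected_indices),
                                                  length(sel2$selected_indices)),
                                 k3 = fus$k3, fused_empty = fused_empty,
                                 n_train = length(tr), n_test = length(te),
                                 seed = seed)),
            class = "classification_experiment")
}

#' @export
print.classification_experiment <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Classification experiment (%s):\n", toupper(m$variant)))
  cat(sprintf("  streams %d/%d -> selected %d/%d -> fused k3 = %d%s\n",
              m$dim_in[1], m$dim_in[2], m$dim_selected[1], m$dim_selected[2],
              m$k3, if (m$fused_empty) " (empty; concatenated)" else ""))
  print(x$report)
  invisible(x)
}
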