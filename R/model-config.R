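#' Model configuration
#'
#' Assembles the hyperparameter list of the hybrid classifier.  Defaults
#' follow the calibrated operating point of the method: four convolutional
#' units (21 to 100 channels, then 100 to 100 three times), a two-round
#' GraphSAGE branch (10 to 100 to 100), an MLP head with 256, 64 and 2
#' neurons, dropout 0.2 throughout, initial learning rate 1e-4, L2
#' coefficient 1e-4, silencer class weight 1.2 and learning-rate decay
#' factor 0.95 applied whenever the training loss rises.
#'
#' @param inChannels Input channels of the linear branch (4 sequence rows +
#'   number of tracks).
#' @param seqLen Window length in nt.
#' @param cnnChannels Output channels of the consecutive convolutional
#'   units.
#' @param kernel Convolution kernel width (same-padding, stride 1).
#' @param pool Max-pooling width per unit (stride equal to width; the
#'   remainder of a window not filling a pool is dropped).
#' @param descriptorDim Node descriptor length (GraphSAGE input).
#' @param sageChannels Output dimensions of the GraphSAGE rounds.
#' @param mlp Sizes of the fully connected head; the last entry must be 2.
#' @param dropout Dropout rate applied after every unit during training.
#' @param leakySlope Negative slope of the LeakyReLU activations.
#' @param lr Initial learning rate (Adam).
#' @param l2 L2 regularization coefficient on weight matrices.
#' @param classWeight Loss weight of the silencer class.
#' @param gamma Learning-rate decay factor on a training-loss rise.
#' @param maxEpochs Maximum training epochs.
#' @param patience Epochs without validation-loss improvement before
#'   stopping (ignored when `valFraction` is 0).
#' @param batchSize Minibatch size.
#' @param valFraction Fraction of training nodes held out for early
#'   stopping.
#' @param seed Integer seed controlling initialization, batching and
#'   dropout.
#' @return A named list of class `"reinConfig"`.
#' @export
reinConfig <- function(inChannels = 21L, seqLen = 600L,
                       cnnChannels = c(100L, 100L, 100L, 100L), kernel = 8L,
                       pool = 4L, descriptorDim = 10L,
                       sageChannels = c(100L, 100L), mlp = c(256L, 64L, 2L),
                       dropout = 0.2, leakySlope = 0.01, lr = 1e-4, l2 = 1e-4,
                       classWeight = 1.2, gamma = 0.95, maxEpochs = 100L,
                       patience = 10L, batchSize = 32L, valFraction = 0.15,
                       seed = 1L) {
  cfg <- list(inChannels = as.integer(inChannels), seqLen = as.integer(seqLen),
              cnnChannels = as.integer(cnnChannels), kernel = as.integer(kernel),
              pool = as.integer(pool), descriptorDim = as.integer(descriptorDim),
              sageChannels = as.integer(sageChannels), mlp = as.integer(mlp),
              dropout = dropout, leakySlope = leakySlope, lr = lr, l2 = l2,
              classWeight = classWeight, gamma = gamma,
              maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
              batchSize = as.integer(batchSize), valFraction = valFraction,
              seed = as.integer(seed))
  if (cfg$mlp[length(cfg$mlp)] != 2L)
    stopf("the MLP head must end in 2 output neurons")
  stopifnot(cfg$kernel >= 1L, cfg$pool >= 1L, cfg$lr > 0, cfg$l2 >= 0,
            cfg$classWeight > 0, cfg$gamma > 0, cfg$gamma <= 1,
            cfg$dropout >= 0, cfg$dropout < 1)
  class(cfg) <- "reinConfig"
  cfg
}
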