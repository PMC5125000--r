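1 1 1 1 1 1 1 1 1 1 0 0 0 0 0 0 0 0 0 0
cg_1_00001 1 100000 0.109 0.223 0.777 0.114 0.988 0.71 0.937 0.074 0.122 0.186 0.675 0.831 0.788 0.89 0.776 0.74 0.8 0.302 0.861 0.041
cg_1_00002 1 102000 0.828 0.723 0.785 0.071 0.835 0.892 0.29 0.676 0.122 0.683 0.917 0.993 0.088 0.891 0.833 0.771 0.123 0.291 0.706 0.377
cg_1_00003 1 104000 0.262 0.744 0.912 0.793 0.19 0.015 0.184 0.631 0.079 0.857 0.745 0.315 0.921 0.79 0.797 0.886 0.918 0.582 0.373 0.221
cg_1_00004 1 106000 0.138 0.91 0.857 0.972 0.055 0.189 0.259 0.538 0.132 0.879 0.742 0.291 0.711 0.696 0.811 0.753 0.957 0.524 0.143 0.175
cg_1_00005 1 108000 0.368 0.894 0.7 0.764 0.275 0.156 0.158 0.819 0.15 0.911 0.736 0.229 0.919 0.939 0.786 0.87 0.761 0.916 0.243 0.137
cg_1_00006 1 110000 0.73 0.812 0.777 0.735 0.327 0.249 0.785 0.928 0.218 0.295 0.66 0.764 0.95 0.413 0.757 0.908 0.081 0.159 0.846 0.707
cg_1_00007 1 112000 0.107 0.247 0.794 0.081 0.748 0.917 0.877 0.87 0.877 0.291 0.774 0.185 0.668 0.883 0.257 0.4 0.353 0.232 0.282 0.143
cg_1_00008 1 114000 0.055 0.339 0.921 0.189 0.611 0.736 0.13 0.2 0.314 0.188 0.32 0.712 0.121 0.79 0.798 0.154 0.269 0.768 0.858 0.627
cg_2_00001 2 500000 0.212 0.284 0.858 0.186 0.822 0.748 0.691 0.214 0.713 0.77 0.761 0.254 0.928 0.94 0.776 0.66 0.883 0.934 0.166 0.201
cg_2_00002 2 503000 0.82 0.017 0.87 0.17 0.875 0.923 0.281 0.175 0.425 0.74 0.822 0.798 0.122 0.705 0.224 0.802 0.775 0.913 0.351 0.346
cg_2_00003 2 506000 0.821 0.122 0.351 0.173 0.363 0.027 0.809 0.089 0.229 0.01 0.688 0.221 0.831 0.687 0.042 0.698 0.807 0.86 0.021 0.714
cg_2_00004 2 509000 0.178 0.835 0.717 0.319 0.071 0.071 0.294 0.008 0.135 0.853 0.91 0.817 0.825 0.247 0.884 0.311 0.409 0.815 0.782 0.724
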