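MODEL        1
ATOM      1  N   ALA A   1       0.014   0.517   0.048  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.127   0.108  -0.402  1.00  0.00           C
ATOM      3  C   ALA A   1       2.171   1.513  -0.153  1.00  0.00           C
ATOM      4  O   ALA A   1       1.778   2.137  -1.858  1.00  0.00           O
ATOM      5  N   ALA A   2       2.739   1.928   1.363  1.00  0.00           N
ATOM      6  CA  ALA A   2       4.011   3.213   1.208  1.00  0.00           C
ATOM      7  C   ALA A   2       4.698   2.658   0.823  1.00  0.00           C
ATOM      8  O   ALA A   2       5.785   2.140   1.522  1.00  0.00           O
ATOM      9  N   ALA A   3       5.239   4.436  -0.299  1.00  0.00           N
ATOM     10  CA  ALA A   3       7.477   3.889  -0.441  1.00  0.00           C
ATOM     11  C   ALA A   3       7.598   4.940   0.506  1.00  0.00           C
ATOM     12  O   ALA A   3       7.456   6.521  -0.257  1.00  0.00           O
ATOM     13  N   ALA A   4       8.980   4.990  -0.133  1.00  0.00           N
ATOM     14  CA  ALA A   4       9.619   6.116   1.398  1.00  0.00           C
ATOM     15  C   ALA A   4      10.933   6.461   0.550  1.00  0.00           C
ATOM     16  O   ALA A   4      11.841   5.703   0.801  1.00  0.00           O
ATOM     17  N   ALA A   5      10.903   7.482  -0.178  1.00  0.00           N
ATOM     18  CA  ALA A   5      12.575   6.854  -0.328  1.00  0.00           C
ATOM     19  C   ALA A   5      13.140   8.651  -0.073  1.00  0.00           C
ATOM     20  O   ALA A   5      13.211  10.160   0.101  1.00  0.00           O
ENDMDL
MODEL        2
ATOM      1  N   ALA A   1      -0.080  -0.275  -0.044  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.992  -0.143  -0.012  1.00  0.00           C
ATOM      3  C   ALA A   1       2.188   1.154  -0.193  1.00  0.00           C
ATOM      4  O   ALA A   1       1.682   2.188  -0.695  1.00  0.00           O
ATOM      5  N   ALA A   2       3.396   1.677   0.449  1.00  0.00           N
ATOM      6  CA  ALA A   2       3.605   2.683   1.317  1.00  0.00           C
ATOM      7  C   ALA A   2       4.692   3.013   0.699  1.00  0.00           C
ATOM      8  O   ALA A   2       5.834   2.349   1.803  1.00  0.00           O
ATOM      9  N   ALA A   3       5.144   4.129  -0.349  1.00  0.00           N
ATOM     10  CA  ALA A   3       7.224   3.645   0.174  1.00  0.00           C
ATOM     11  C   ALA A   3       7.859   5.404   0.247  1.00  0.00           C
ATOM     12  O   ALA A   3       7.540   6.482  -0.712  1.00  0.00           O
ATOM     13  N   ALA A   4       8.374   5.034   0.512  1.00  0.00           N
ATOM     14  CA  ALA A   4       9.217   6.675   0.804  1.00  0.00           C
ATOM     15  C   ALA A   4      10.708   6.138  -0.047  1.00  0.00           C
ATOM     16  O   ALA A   4      11.778   5.045   1.030  1.00  0.00           O
ATOM     17  N   ALA A   5      10.579   7.213   0.271  1.00  0.00           N
ATOM     18  CA  ALA A   5      12.630   7.925  -0.672  1.00  0.00           C
ATOM     19  C   ALA A   5      13.227   8.965   0.041  1.00  0.00           C
ATOM     20  O   ALA A   5      12.375  10.005  -0.208  1.00  0.00           O
ENDMDL
MODEL        3
ATOM      1  N   ALA A   1      -0.014  -0.285   0.455  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.147  -0.624   0.301  1.00  0.00           C
ATOM      3  C   ALA A   1       2.477   0.856   0.203  1.00  0.00           C
ATOM      4  O   ALA A   1       1.339   2.441  -1.657  1.00  0.00           O
ATOM      5  N   ALA A   2       2.959   1.605   0.837  1.00  0.00           N
ATOM      6  CA  ALA A   2       3.796   2.610   1.006  1.00  0.00           C
ATOM      7  C   ALA A   2       5.084   3.021   0.669  1.00  0.00           C
ATOM      8  O   ALA A   2       5.830   1.575   1.267  1.00  0.00           O
ATOM      9  N   ALA A   3       5.218   3.759  -0.465  1.00  0.00           N
ATOM     10  CA  ALA A   3       7.475   3.705  -0.464  1.00  0.00           C
ATOM     11  C   ALA A   3       7.257   5.648  -0.550  1.00  0.00           C
ATOM     12  O   ALA A   3       6.814   5.937  -0.540  1.00  0.00           O
ATOM     13  N   ALA A   4       9.049   5.050   1.121  1.00  0.00           N
ATOM     14  CA  ALA A   4       9.591   7.052   1.161  1.00  0.00           C
ATOM     15  C   ALA A   4      10.458   6.080   0.293  1.00  0.00           C
ATOM     16  O   ALA A   4      11.424   5.973   0.755  1.00  0.00           O
ATOM     17  N   ALA A   5      11.075   7.696   0.431  1.00  0.00           N
ATOM     18  CA  ALA A   5      12.389   8.448  -0.635  1.00  0.00           C
ATOM     19  C   ALA A   5      12.695   8.871   0.112  1.00  0.00           C
ATOM     20  O   ALA A   5      13.264   9.873   0.648  1.00  0.00           O
ENDMDL
END
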