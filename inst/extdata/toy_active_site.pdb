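CRYST1   80.000   96.000  105.000  90.00  90.00  90.00 I 2 2 2    
HETATM    1  C5  AZA A 301       1.390   0.000   0.000  1.00 10.00           C
HETATM    2  C4  AZA A 301       0.695   1.204   0.000  1.00 10.00           C
HETATM    3  N3  AZA A 301      -0.695   1.204   0.000  1.00 10.00           N
HETATM    4  C2  AZA A 301      -1.390   0.000   0.000  1.00 10.00           C
HETATM    5  N1  AZA A 301      -0.695  -1.204   0.000  1.00 10.00           N
HETATM    6  C6  AZA A 301       0.695  -1.204   0.000  1.00 10.00           C
HETATM    7  N7  AZA A 301       2.750   0.289   0.000  1.00 10.00           N
HETATM    8  N8  AZA A 301       2.895   1.671   0.000  1.00 10.00           N
HETATM    9  N9  AZA A 301       1.625   2.237   0.000  1.00 10.00           N
HETATM   10  O6  AZA A 301       1.310  -2.269   0.000  1.00 10.00           O
HETATM   11  O2  AZA A 301      -2.620   0.000   0.000  1.00 10.00           O
HETATM   12  D1  AZA A 301      -1.200  -2.078   0.000  1.00 10.00           D
HETATM   13  D9  AZA A 301       1.415   3.225   0.000  1.00 10.00           D
ATOM     14  N   THR B  57       5.523  -0.785  -4.490  1.00 10.00           N
ATOM     15  CA  THR B  57       5.988   0.001  -3.350  1.00 10.00           C
ATOM     16  C   THR B  57       6.979   1.084  -3.743  1.00 10.00           C
ATOM     17  O   THR B  57       6.749   2.259  -3.462  1.00 10.00           O
ATOM     18  CB  THR B  57       4.795   0.622  -2.622  1.00 10.00           C
ATOM     19  OG1 THR B  57       3.928  -0.415  -2.155  1.00 10.00           O
ATOM     20  DG1 THR B  57       3.111  -0.399  -2.659  0.78 10.00           D
ATOM     21  CE  LYS B  10       3.756  -3.515  -3.942  1.00 10.00           C
ATOM     22  NZ  LYS B  10       4.198  -3.346  -2.529  1.00 10.00           N
ATOM     23  DZ1 LYS B  10       4.254  -2.352  -2.307  1.00 10.00           D
ATOM     24  DZ2 LYS B  10       5.116  -3.773  -2.407  1.00 10.00           D
ATOM     25  DZ3 LYS B  10       3.528  -3.797  -1.906  1.00 10.00           D
ATOM     26  N   ASN A 254      -4.630  -3.892  -2.504  1.00 10.00           N
ATOM     27  CA  ASN A 254      -4.284  -2.477  -2.601  1.00 10.00           C
ATOM     28  CB  ASN A 254      -2.908  -2.318  -3.252  1.00 10.00           C
ATOM     29  CG AASN A 254      -1.190  -3.382  -2.044  0.75 10.00           C
ATOM     30  OD1AASN A 254      -1.992  -4.194  -1.585  0.75 10.00           O
ATOM     31  ND2AASN A 254      -0.357  -3.694  -3.032  0.75 10.00           N
ATOM     32 DD21AASN A 254       0.289  -3.003  -3.386  0.75 10.00           D
ATOM     33 DD22AASN A 254      -0.371  -4.623  -3.430  0.75 10.00           D
ATOM     34  CG BASN A 254      -2.277  -0.318  -4.398  0.25 10.00           C
ATOM     35  OD1BASN A 254      -3.435  -0.082  -4.738  0.25 10.00           O
ATOM     36  ND2BASN A 254      -1.565  -1.295  -4.953  0.25 10.00           N
ATOM     37 DD21BASN A 254      -0.616  -1.462  -4.650  0.25 10.00           D
ATOM     38 DD22BASN A 254      -1.973  -1.869  -5.676  0.25 10.00           D
HETATM   39  O   HOH S 401       1.130  -0.939  -3.330  0.93 10.00           O
HETATM   40  D1  HOH S 401       1.378  -0.132  -3.787  0.93 10.00           D
HETATM   41  D2  HOH S 401       0.431  -0.670  -2.730  0.93 10.00           D
HETATM   42  O   HOH S 402       1.351   5.064   0.000  1.00 10.00           O
END
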