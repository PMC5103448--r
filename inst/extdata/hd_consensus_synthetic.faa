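>Hox1 synthetic homeodomain consensus group=Hox1
RASGQGGWTRYQTLELEKEFHFNRYLTRVRRIEIAHALCLTERQIKIWFQNRRMKCKKEN
>Hox2 synthetic homeodomain consensus group=Hox2
RTRNRQTYTRYQTLELEKEFHFNSYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKGAN
>Hox3 synthetic homeodomain consensus group=Hox3
RKRTRQTYTRYQTPELEKEFHFNRYLTRRRRIEIAALLCLTERQIKIWFQNRRMKWKKEN
>Hox4 synthetic homeodomain consensus group=Hox4
RKRGQQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKKEN
>Hox5 synthetic homeodomain consensus group=Hox5
RKRGQQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKKEN
>Lox5 synthetic homeodomain consensus group=Lox5
RKRGQQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKKEN
>Antp synthetic homeodomain consensus group=Antp
RKRGQQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKKEN
>Lox4 synthetic homeodomain consensus group=Lox4
RKRGQQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKKEN
>Lox2 synthetic homeodomain consensus group=Lox2
RKRGQQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKKEN
>Post2 synthetic homeodomain consensus group=Post2
RKRGQQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKKEN
>Post1 synthetic homeodomain consensus group=Post1
RKRGQQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKKEN
>Gsx synthetic homeodomain consensus group=Gsx
RKRGQQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKKEN
>Xlox synthetic homeodomain consensus group=Xlox
RKRGQQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKKEN
>Cdx synthetic homeodomain consensus group=Cdx
RKRGQQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKKEN
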