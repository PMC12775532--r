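ve
bir
bu
şu
o
da
de
ki
mi
mu
ne
ama
için
ile
gibi
çok
daha
en
ya
hem
ise
diye
kadar
sonra
önce
şey
var
yok
evet
hayır
ben
sen
biz
siz
onlar
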